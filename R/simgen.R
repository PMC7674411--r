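#' Configuration for the synthetic dioecious-genome generator
#'
#' Defines a desk-scale dioecious population anchored at the operating point
#' of a typical poplar sex-determination resequencing study: 49 females and
#' 46 males at 20x depth, a peritelomeric 299-kb sex-linked region (SLR)
#' with diverged X/Y haplotypes, Y-hemizygous insertions (YHSs) of 34.8 kb,
#' 4.3 kb and 100 bp, one autosomal paralog of YHS sequence that attracts
#' cross-mapped reads when the reference lacks the YHS, and tunable
#' genotype noise.
#'
#' Coordinates are 0-based half-open.  `yhs_intervals` are expressed in
#' X-haplotype ("planning") coordinates: the interval `[s, e)` means that
#' the Y haplotype carries an extra segment of length `e - s` inserted
#' immediately before X position `s`; the segment has no X counterpart.
#' The SLR must abut the end of the sex chromosome (it is peritelomeric),
#' which guarantees that coordinates outside the SLR are identical under
#' the female and Y-substituted references.
#'
#' @param n_females,n_males population sizes per sex.
#' @param chrom_lengths named integer vector of chromosome lengths in bp;
#'   the first chromosome is the sex chromosome.
#' @param slr_interval 0-based half-open interval of the SLR on the sex
#'   chromosome; must end at the chromosome end.
#' @param yhs_intervals list of planning-coordinate intervals (see above)
#'   inside the SLR, present only on the Y haplotype.
#' @param paralog_map list of `list(source =, target_chrom =, target =,
#'   identity =)` entries: `source` is a planning-coordinate interval inside
#'   a YHS whose sequence is copied (at the given identity fraction) into
#'   the autosomal `target` interval of the reference.
#' @param snp_density expected background SNPs per bp outside the SLR.
#' @param xy_divergence per-bp substitution rate between the X and Y
#'   haplotypes inside the SLR (these sites are the true SEMS).
#' @param mean_depth expected read depth of a diploid window (reads per
#'   window); a hemizygous copy receives half of this.
#' @param mismap_fraction fraction (mu) of reads from a Y-hemizygous source
#'   that map onto its paralog when the reference lacks the source.
#' @param missing_rate,genotype_error_rate per-genotype corruption rates.
#' @param window_size coverage window size in bp.
#' @param min_alt_reads minimum cross-mapped reads required for the variant
#'   caller model to emit a heterozygous call at an artifact site.
#' @param depth_scale optional per-sample depth multipliers (length
#'   `n_females + n_males`); default uniform.
#' @param overdispersion optional negative-binomial size parameter for
#'   window depths; `NULL` (default) draws Poisson depths.
#' @param system `"XY"` (male heterogamety, default) or `"ZW"` (female
#'   heterogamety; the roles of the sexes are exchanged throughout).
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_females = 49L, n_males = 46L,
                       chrom_lengths = c(chr19 = 1000000L, chr09 = 500000L),
                       slr_interval = c(701000L, 1000000L),
                       yhs_intervals = list(
                         YHS1 = c(720000L, 754800L),
                         YHS2 = c(800000L, 804300L),
                         YHS3 = c(850000L, 850100L)),
                       paralog_map = list(
                         list(source = c(720000L, 722000L),
                              target_chrom = "chr09",
                              target = c(100000L, 102000L),
                              identity = 0.95)),
                       snp_density = 0.001,
                       xy_divergence = 0.0015,
                       mean_depth = 20,
                       mismap_fraction = 0.8,
                       missing_rate = 0,
                       genotype_error_rate = 0,
                       window_size = 100L,
                       min_alt_reads = 2L,
                       depth_scale = NULL,
                       overdispersion = NULL,
                       system = c("XY", "ZW"),
                       seed = 1L) {
  system <- match.arg(system)
  if (n_females < 1L || n_males < 1L)
    stopf("need at least one sample of each sex")
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)))
    stopf("chrom_lengths must be named")
  if (mean_depth <= 0) stopf("mean_depth must be positive")
  for (r in c(mismap_fraction, missing_rate, genotype_error_rate))
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  sex_chrom <- names(chrom_lengths)[1]
  check_interval(slr_interval, chrom_lengths[[1]], "slr_interval")
  if (slr_interval[2] != chrom_lengths[[1]])
    stopf("slr_interval must abut the end of the sex chromosome (peritelomeric)")
  if (length(yhs_intervals)) {
    if (is.null(names(yhs_intervals)))
      names(yhs_intervals) <- paste0("YHS", seq_along(yhs_intervals))
    for (nm in names(yhs_intervals)) {
      iv <- yhs_intervals[[nm]]
      if (iv[1] < slr_interval[1] || iv[2] > slr_interval[2] || iv[2] <= iv[1])
        stopf("YHS interval %s must lie within the SLR", nm)
    }
    ivs <- do.call(rbind, yhs_intervals)
    o <- order(ivs[, 1])
    if (length(o) > 1 && any(ivs[o[-length(o)], 2] > ivs[o[-1], 1]))
      stopf("yhs_intervals must be pairwise disjoint")
  }
  if (length(paralog_map)) {
    tg <- lapply(paralog_map, function(p) p$target)
    tc <- vapply(paralog_map, function(p) p$target_chrom, "")
    for (i in seq_along(paralog_map)) {
      p <- paralog_map[[i]]
      if (!p$target_chrom %in% names(chrom_lengths))
        stopf("paralog target chromosome %s unknown", p$target_chrom)
      check_interval(p$target, chrom_lengths[[p$target_chrom]],
                     "paralog target")
      if (p$target_chrom == sex_chrom &&
          interval_overlap(p$target[1], p$target[2],
                           slr_interval[1], slr_interval[2]) > 0)
        stopf("paralog targets must not overlap the SLR")
      if (p$identity < 0 || p$identity > 1) stopf("identity must be in [0, 1]")
      in_yhs <- any(vapply(yhs_intervals, function(iv)
        p$source[1] >= iv[1] && p$source[2] <= iv[2], TRUE))
      if (!in_yhs) stopf("paralog source must lie inside a YHS interval")
      for (j in seq_len(i - 1L)) {
        if (tc[j] == tc[i] &&
            interval_overlap(tg[[j]][1], tg[[j]][2],
                             tg[[i]][1], tg[[i]][2]) > 0)
          stopf("paralog targets must not overlap each other")
      }
    }
  }
  ds <- depth_scale %||% rep(1, n_females + n_males)
  if (length(ds) != n_females + n_males)
    stopf("depth_scale must have one entry per sample")
  structure(list(
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    chrom_lengths = chrom_lengths, sex_chrom = sex_chrom,
    slr_interval = as.integer(slr_interval),
    yhs_intervals = yhs_intervals, paralog_map = paralog_map,
    snp_density = snp_density, xy_divergence = xy_divergence,
    mean_depth = mean_depth, mismap_fraction = mismap_fraction,
    missing_rate = missing_rate, genotype_error_rate = genotype_error_rate,
    window_size = as.integer(window_size),
    min_alt_reads = as.integer(min_alt_reads),
    depth_scale = ds, overdispersion = overdispersion,
    system = system, seed = as.integer(seed)), class = "sim_config")
}

# Map an X (planning) coordinate inside the SLR to the Y-substituted
# reference coordinate: every YHS inserted at or before `pos` shifts it.
lift_to_y <- function(pos, yhs_intervals) {
  if (!length(yhs_intervals)) return(pos)
  starts <- vapply(yhs_intervals, `[`, 0L, 1L)
  lens <- vapply(yhs_intervals, function(iv) iv[2] - iv[1], 0L)
  pos + vapply(pos, function(p) sum(lens[starts <= p]), 0L)
}

#' Build the female and Y-substituted references with ground truth
#'
#' Generates a random genome, diverges the Y haplotype from the X inside
#' the SLR, inserts the Y-hemizygous segments, and copies the configured
#' YHS sources into their autosomal paralog targets at the stated identity.
#' The female reference carries the X haplotype in the SLR; the
#' Y-substituted reference is identical except that the SLR is replaced by
#' the Y haplotype.  Both references and the ground truth are reproducible
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with elements `female_reference` and
#'   `y_substituted_reference` (named character vectors of chromosome
#'   sequences) and `truth`, an `slr_truth` list carrying sample sexes,
#'   true SEMS sites (with coordinates under both references), artifact
#'   sites inside the paralog targets, the planted YHS intervals in
#'   Y-reference coordinates, the X and Y SLR haplotypes, and the
#'   designated mother/son trio ids.
#' @export
build_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    ref <- vapply(config$chrom_lengths, random_seq, "")
    names(ref) <- names(config$chrom_lengths)
    slr <- config$slr_interval
    slr_len <- slr[2] - slr[1]
    x_slr <- substr(ref[[config$sex_chrom]], slr[1] + 1L, slr[2])

    div_local <- bernoulli_positions(slr_len, config$xy_divergence)
    mut <- mutate_at(x_slr, div_local)
    y_backbone <- mut$seq

    yhs_seqs <- lapply(config$yhs_intervals,
                       function(iv) random_seq(iv[2] - iv[1]))
    # assemble the Y haplotype: backbone with insertions at planning starts
    if (length(yhs_seqs)) {
      starts <- vapply(config$yhs_intervals, `[`, 0L, 1L)
      o <- order(starts)
      pieces <- character(0)
      cursor <- 0L  # SLR-local
      for (i in o) {
        at <- starts[i] - slr[1]
        pieces <- c(pieces, substr(y_backbone, cursor + 1L, at),
                    yhs_seqs[[i]])
        cursor <- at
      }
      pieces <- c(pieces, substr(y_backbone, cursor + 1L, slr_len))
      y_slr <- paste(pieces, collapse = "")
    } else y_slr <- y_backbone

    # paralogs: copy (mutated) YHS source sequence into autosomal targets
    artifact <- list()
    for (p in config$paralog_map) {
      host <- which(vapply(config$yhs_intervals, function(iv)
        p$source[1] >= iv[1] && p$source[2] <= iv[2], TRUE))[1]
      iv <- config$yhs_intervals[[host]]
      src <- substr(yhs_seqs[[host]], p$source[1] - iv[1] + 1L,
                    p$source[2] - iv[1])
      n_src <- nchar(src)
      mpos <- bernoulli_positions(n_src, 1 - p$identity)
      mm <- mutate_at(src, mpos)
      tseq <- ref[[p$target_chrom]]
      substr(tseq, p$target[1] + 1L, p$target[2]) <- mm$seq
      ref[[p$target_chrom]] <- tseq
      if (length(mpos)) {
        artifact[[length(artifact) + 1L]] <- data.frame(
          chrom = p$target_chrom, pos0 = p$target[1] + mpos,
          ref = mm$new,   # base now in both references
          alt = mm$old,   # base carried by cross-mapped hemizygous reads
          stringsAsFactors = FALSE)
      }
    }
    artifact_sites <- if (length(artifact)) do.call(rbind, artifact) else
      data.frame(chrom = character(0), pos0 = integer(0),
                 ref = character(0), alt = character(0))

    y_ref <- ref
    y_ref[[config$sex_chrom]] <-
      paste0(substr(ref[[config$sex_chrom]], 1L, slr[1]), y_slr)

    total_yhs <- sum(vapply(config$yhs_intervals,
                            function(iv) iv[2] - iv[1], 0L))
    pos0 <- slr[1] + div_local
    true_sems <- data.frame(
      chrom = config$sex_chrom, pos0 = pos0,
      pos0_y = lift_to_y(pos0, config$yhs_intervals),
      x_allele = mut$old, y_allele = mut$new, stringsAsFactors = FALSE)

    true_yhs <- if (length(config$yhs_intervals)) {
      starts <- vapply(config$yhs_intervals, `[`, 0L, 1L)
      lens <- vapply(config$yhs_intervals, function(iv) iv[2] - iv[1], 0L)
      y_start <- lift_to_y(starts, config$yhs_intervals) - lens
      data.frame(name = names(config$yhs_intervals),
                 chrom = config$sex_chrom,
                 start = y_start, end = y_start + lens,
                 insert_point = starts, length = lens,
                 stringsAsFactors = FALSE)
    } else data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      insert_point = integer(0), length = integer(0))

    het <- if (config$system == "XY") "M" else "F"
    hom <- if (config$system == "XY") "F" else "M"
    ids_hom <- sprintf("%s%02d", hom, seq_len(
      if (hom == "F") config$n_females else config$n_males))
    ids_het <- sprintf("%s%02d", het, seq_len(
      if (het == "F") config$n_females else config$n_males))
    sex_of <- c(setNames(rep(hom, length(ids_hom)), ids_hom),
                setNames(rep(het, length(ids_het)), ids_het))

    truth <- structure(list(
      sex_of = sex_of, true_sems = true_sems,
      artifact_sites = artifact_sites, true_yhs = true_yhs,
      x_haplotype = x_slr, y_haplotype = y_slr,
      slr_interval = slr,
      slr_interval_y = c(slr[1], slr[2] + total_yhs),
      mother_id = "mother", son_id = "son",
      config = config), class = "slr_truth")
    list(female_reference = ref, y_substituted_reference = y_ref,
         truth = truth)
  })
}

# depth draw honouring the optional negative-binomial switch
draw_depth <- function(lambda, overdispersion) {
  bad <- !is.finite(lambda) | lambda < 0
  lambda[bad] <- 0
  if (is.null(overdispersion)) rpois(length(lambda), lambda)
  else stats::rnbinom(length(lambda), size = overdispersion, mu = lambda)
}

#' Simulate population genotype calls and windowed coverage
#'
#' Draws the observable artifacts the discovery pipeline consumes, under
#' either the female reference or the Y-substituted reference.  Window
#' depths are Poisson with mean `mean_depth * c/2`, where `c` is the
#' sample's copy number of the window relative to the chosen reference
#' (2 diploid; at YHS windows of the Y-substituted reference, 1 for the
#' heterogametic sex and 0 for the homogametic sex).  Under the female
#' reference, paralog-target windows additionally receive
#' Poisson(mu * mean_depth/2) cross-mapped depth in the heterogametic sex,
#' and each artifact site is called heterozygous in a heterogametic sample
#' when at least `min_alt_reads` cross-mapped reads arrive (a Poisson
#' tail).  Genotypes at true SEMS sites follow the fully sex-linked
#' pattern before missingness/error corruption.  Deterministic given
#' `config$seed`; population haplotype draws are shared between the two
#' reference modes so that sites outside the SLR agree across references.
#'
#' @param config a [sim_config()].
#' @param truth the `slr_truth` produced by [build_references()] with the
#'   same config.
#' @param reference_mode `"female"` or `"y_substituted"`.
#' @return list with `genotypes` (a `genotype_matrix`), `coverage` (a
#'   `coverage_matrix`) and `sex` (a data.frame of sample, sex).
#' @export
simulate_population <- function(config, truth,
                                reference_mode = c("female", "y_substituted")) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "slr_truth"))
  reference_mode <- match.arg(reference_mode)
  if (!identical(truth$config$seed, config$seed) ||
      !identical(truth$config$chrom_lengths, config$chrom_lengths))
    stopf("truth was not produced by build_references() with this config")

  samples <- names(truth$sex_of)
  sexes <- unname(truth$sex_of)
  het_sex <- if (config$system == "XY") "M" else "F"
  is_het <- sexes == het_sex
  n <- length(samples)

  ## ---- sites shared between reference modes ----
  shared <- with_seed(config$seed + 2L, {
    sites <- list(); geno <- list()
    ts <- truth$true_sems
    if (nrow(ts)) {
      g <- matrix(0L, nrow(ts), n)
      g[, is_het] <- 1L
      if (reference_mode == "female") {
        sites$sems <- data.frame(chrom = ts$chrom, pos0 = ts$pos0,
                                 ref = ts$x_allele, alt = ts$y_allele,
                                 stringsAsFactors = FALSE)
      } else {
        g[, !is_het] <- 2L  # homogametic sex is ALT/ALT against the Y allele
        sites$sems <- data.frame(chrom = ts$chrom, pos0 = ts$pos0_y,
                                 ref = ts$y_allele, alt = ts$x_allele,
                                 stringsAsFactors = FALSE)
      }
      geno$sems <- g
    }
    # background SNPs: HWE draws outside the SLR (identical in both modes)
    bg_sites <- list(); bg_geno <- list()
    for (chrom in names(config$chrom_lengths)) {
      len <- config$chrom_lengths[[chrom]]
      if (chrom == config$sex_chrom) len <- config$slr_interval[1]
      pos <- bernoulli_positions(len, config$snp_density)
      pos <- setdiff(pos, truth$artifact_sites$pos0[
        truth$artifact_sites$chrom == chrom])
      if (!length(pos)) next
      p_alt <- runif(length(pos), 0.05, 0.95)
      g <- matrix(rbinom(length(pos) * n, 2L, rep(p_alt, n)),
                  nrow = length(pos))
      ra <- sample(DNA_BASES, length(pos), replace = TRUE)
      aa <- vapply(ra, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      bg_sites[[chrom]] <- data.frame(chrom = chrom, pos0 = pos,
                                      ref = ra, alt = unname(aa),
                                      stringsAsFactors = FALSE)
      bg_geno[[chrom]] <- g
    }
    if (length(bg_sites)) {
      sites$bg <- do.call(rbind, bg_sites)
      geno$bg <- do.call(rbind, bg_geno)
    }
    list(sites = sites, geno = geno)
  })

  sites <- shared$sites; geno <- shared$geno

  ## ---- cross-mapping artifact calls (female reference only) ----
  if (reference_mode == "female" && nrow(truth$artifact_sites) &&
      config$mismap_fraction > 0) {
    with_seed(config$seed + 5L, {
      as_ <- truth$artifact_sites
      p_het <- 1 - ppois(config$min_alt_reads - 1L,
                         config$mismap_fraction * config$mean_depth / 2)
      g <- matrix(0L, nrow(as_), n)
      g[, is_het] <- matrix(
        rbinom(nrow(as_) * sum(is_het), 1L, p_het), nrow = nrow(as_))
      keep <- rowSums(g) > 0L  # a caller emits no record for monomorphic sites
      if (any(keep)) {
        sites$artifact <- data.frame(chrom = as_$chrom[keep],
                                     pos0 = as_$pos0[keep],
                                     ref = as_$ref[keep], alt = as_$alt[keep],
                                     stringsAsFactors = FALSE)
        geno$artifact <- g[keep, , drop = FALSE]
      }
    })
  }

  site_df <- do.call(rbind, unname(sites))
  gmat <- do.call(rbind, unname(geno))
  chrom_rank <- match(site_df$chrom, names(config$chrom_lengths))
  o <- order(chrom_rank, site_df$pos0)
  site_df <- site_df[o, , drop = FALSE]
  gmat <- gmat[o, , drop = FALSE]
  rownames(site_df) <- NULL

  ## ---- genotype corruption ----
  mode_off <- if (reference_mode == "female") 6L else 7L
  with_seed(config$seed + mode_off, {
    ncell <- length(gmat)
    if (config$genotype_error_rate > 0 && ncell) {
      err <- which(runif(ncell) < config$genotype_error_rate)
      if (length(err))
        gmat[err] <- (gmat[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    }
    if (config$missing_rate > 0 && ncell)
      gmat[runif(ncell) < config$missing_rate] <- NA_integer_
  })

  genotypes <- genotype_matrix(site_df, gmat, samples)

  ## ---- coverage ----
  chrom_lengths <- config$chrom_lengths
  if (reference_mode == "y_substituted")
    chrom_lengths[[config$sex_chrom]] <-
      chrom_lengths[[config$sex_chrom]] + sum(truth$true_yhs$length)
  grid <- window_grid(chrom_lengths, config$window_size)
  nw <- nrow(grid)
  width <- grid$end - grid$start

  c_het <- rep(2, nw); c_hom <- rep(2, nw)
  if (reference_mode == "y_substituted" && nrow(truth$true_yhs)) {
    on_sex <- grid$chrom == config$sex_chrom
    ov <- numeric(nw)
    for (i in seq_len(nrow(truth$true_yhs)))
      ov[on_sex] <- ov[on_sex] + interval_overlap(
        grid$start[on_sex], grid$end[on_sex],
        truth$true_yhs$start[i], truth$true_yhs$end[i])
    frac <- ov / width
    c_het <- 2 - frac        # hemizygous: one copy over the YHS part
    c_hom <- 2 - 2 * frac    # absent entirely
  }
  lam <- matrix(0, nw, n)
  base <- config$mean_depth / 2
  for (j in seq_len(n))
    lam[, j] <- base * (if (is_het[j]) c_het else c_hom) *
      config$depth_scale[j]
  with_seed(config$seed + 3L + (reference_mode == "y_substituted"), {
    depth <- matrix(draw_depth(lam, config$overdispersion), nw, n)
    if (reference_mode == "female" && length(config$paralog_map) &&
        config$mismap_fraction > 0) {
      ovp <- numeric(nw)
      for (p in config$paralog_map) {
        on_t <- grid$chrom == p$target_chrom
        ovp[on_t] <- ovp[on_t] + interval_overlap(
          grid$start[on_t], grid$end[on_t], p$target[1], p$target[2])
      }
      hot <- which(ovp > 0)
      if (length(hot)) {
        extra_lam <- config$mismap_fraction * base * ovp[hot] / width[hot]
        for (j in which(is_het))
          depth[hot, j] <- depth[hot, j] +
            draw_depth(extra_lam * config$depth_scale[j],
                       config$overdispersion)
      }
    }
    coverage <- coverage_matrix(grid, depth, samples)
    list(genotypes = genotypes, coverage = coverage,
         sex = data.frame(sample = samples, sex = sexes,
                          stringsAsFactors = FALSE))
  })
}

#' Simulate a mother-son trio over the SLR
#'
#' The son's X haplotype is, by construction, the reference X (he inherited
#' it from the sequenced mother); his other haplotype is the truth Y.  The
#' mother's second, untransmitted X carries the Y-like allele at a
#' Bernoulli(`mother_het`) subset of the X/Y-divergent sites, modelling
#' shared ancestral polymorphism and giving her an SLR heterozygosity of
#' `mother_het`.
#'
#' @param config a [sim_config()].
#' @param truth matching `slr_truth`.
#' @param mother_het mother's per-site SLR heterozygosity in `[0, 1]`.
#' @param mother_missing per-site probability that the mother's call is
#'   missing.
#' @return an `slr_trio` list: `sites` (chrom, pos0, ref, alt in
#'   female-reference coordinates), `mother` and `son` genotype codes
#'   (0 = hom ref, 1 = het, 2 = hom alt, NA = missing), `slr_interval`,
#'   and the truth attributes `het_sites` (indices where the mother is
#'   heterozygous).
#' @export
simulate_trio <- function(config, truth, mother_het = 0, mother_missing = 0) {
  stopifnot(inherits(truth, "slr_truth"))
  ts <- truth$true_sems
  if (!nrow(ts)) stopf("truth carries no SLR divergence sites to phase")
  with_seed(config$seed + 8L, {
    m <- nrow(ts)
    het_sites <- which(runif(m) < mother_het)
    mother <- rep(0L, m)          # X1 = reference X allele everywhere
    mother[het_sites] <- 1L       # untransmitted X2 carries the Y-like allele
    if (mother_missing > 0)
      mother[runif(m) < mother_missing] <- NA_integer_
    son <- rep(1L, m)             # X(ref allele) + Y(alt allele)
    structure(list(
      sites = data.frame(chrom = ts$chrom, pos0 = ts$pos0,
                         ref = ts$x_allele, alt = ts$y_allele,
                         stringsAsFactors = FALSE),
      mother = mother, son = son,
      slr_interval = truth$slr_interval,
      het_sites = het_sites), class = "slr_trio")
  })
}

#' Construct a chimeric duplicate from labeled progenitor segments
#'
#' Concatenates selected progenitor subsequences in a stated order (labels
#' may repeat, as chimeric duplicates often reuse promoter/exon segments),
#' optionally applying point mutations, and records the exact breakpoint
#' layout as ground truth for decomposition tests.
#'
#' @param segments named list; each element is `list(seq =, interval =)`
#'   giving a source sequence and a 0-based half-open interval within it.
#' @param order character vector of segment labels (repeats allowed).
#' @param mutation_rate per-bp substitution rate applied to the chimera.
#' @param seed RNG seed for the mutations.
#' @return list with `chimera` (sequence) and `truth_layout` (data.frame of
#'   label, chimera_start, chimera_end, source_start, source_end).
#' @export
make_chimeric_duplicate <- function(segments, order, mutation_rate = 0,
                                    seed = 1L) {
  if (!length(segments) || !length(order)) stopf("need at least one segment")
  if (is.null(names(segments))) stopf("segments must be named")
  if (!all(order %in% names(segments))) stopf("unknown label in order")
  parts <- character(length(order))
  layout <- vector("list", length(order))
  at <- 0L
  for (i in seq_along(order)) {
    sg <- segments[[order[i]]]
    check_interval(sg$interval, nchar(sg$seq), "segment interval")
    piece <- substr(sg$seq, sg$interval[1] + 1L, sg$interval[2])
    parts[i] <- piece
    layout[[i]] <- data.frame(label = order[i],
                              chimera_start = at,
                              chimera_end = at + nchar(piece),
                              source_start = sg$interval[1],
                              source_end = sg$interval[2],
                              stringsAsFactors = FALSE)
    at <- at + nchar(piece)
  }
  chimera <- paste(parts, collapse = "")
  if (mutation_rate > 0) {
    chimera <- with_seed(seed, {
      pos <- bernoulli_positions(nchar(chimera), mutation_rate)
      if (length(pos)) mutate_at(chimera, pos)$seq else chimera
    })
  }
  list(chimera = chimera, truth_layout = do.call(rbind, layout))
}
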