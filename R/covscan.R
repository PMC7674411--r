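#' Tile chromosomes into non-overlapping windows
#'
#' Windows are 0-based half-open, tiled from 0; the last window of each
#' chromosome may be short.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window_size window size in bp (default 100).
#' @return data.frame with columns chrom, start, end.
#' @export
window_grid <- function(chrom_lengths, window_size = 100L) {
  stopifnot(window_size >= 1L, all(chrom_lengths >= 1L))
  out <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Construct a windowed coverage matrix
#'
#' @param grid window grid from [window_grid()].
#' @param depth non-negative integer matrix, windows x samples.
#' @param sample_ids character vector of sample names.
#' @return an object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(grid, depth, sample_ids) {
  stopifnot(is.data.frame(grid), nrow(grid) == nrow(depth),
            ncol(depth) == length(sample_ids))
  if (any(depth < 0, na.rm = TRUE)) stopf("depth must be non-negative")
  colnames(depth) <- sample_ids
  structure(list(grid = grid, depth = depth, sample_ids = sample_ids),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %d windows x %d samples (mean depth %.1f)\n",
              nrow(x$grid), length(x$sample_ids), mean(x$depth)))
  invisible(x)
}

#' Three-level categorisation of window read depth
#'
#' Depth 0 maps to category 0 (no read), 1-2 to category 1, and >= 3 to
#' category 2 (a reliable number of reads for presence calling).
#'
#' @param cov a [coverage_matrix()], or a bare numeric matrix/vector of
#'   depths.
#' @return the same shape with categories in \{0, 1, 2\}; for a
#'   `coverage_matrix` input, a `category_matrix` object.
#' @export
categorize_depth <- function(cov) {
  depth_to_cat <- function(d) {
    if (any(d < 0, na.rm = TRUE)) stopf("negative depth")
    x <- ifelse(d >= 3, 2L, ifelse(d >= 1, 1L, 0L))
    if (!is.null(dim(d))) dim(x) <- dim(d)
    x
  }
  if (inherits(cov, "coverage_matrix")) {
    structure(list(grid = cov$grid, categories = depth_to_cat(cov$depth),
                   sample_ids = cov$sample_ids), class = "category_matrix")
  } else depth_to_cat(cov)
}

#' Flag windows whose presence/absence separates the sexes
#'
#' In `strict` mode a window is `male_specific` iff every male is category
#' 2 and every female is category 0 (mirror for `female_specific`): the
#' exact presence/absence signature of a hemizygous insertion on the
#' haplotype carried only by the heterogametic sex.  In `relaxed` mode
#' categories collapse to present (>= 1) / absent (0), a two-sided Fisher
#' exact p-value is computed per window, and a window is flagged when it
#' passes the Bonferroni cutoff and the directional perfect-separation
#' check relaxed to the declared tolerances.
#'
#' @param cats a `category_matrix` from [categorize_depth()].
#' @param sex_table data.frame of sample, sex covering all samples.
#' @param mode `"strict"` or `"relaxed"`.
#' @param alpha family-wise significance level for the relaxed mode.
#' @param min_present_fraction minimum fraction of presence-sex samples
#'   that must be present (relaxed mode).
#' @param max_absent_leak maximum fraction of absence-sex samples allowed
#'   to show any read (relaxed mode).
#' @return data.frame with per-window `flag` in \{male_specific,
#'   female_specific, none\} and, in relaxed mode, the Fisher `p`.
#' @export
window_sex_match <- function(cats, sex_table, mode = c("strict", "relaxed"),
                             alpha = 0.01,
                             min_present_fraction = 0.9,
                             max_absent_leak = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(cats, "category_matrix"))
  sex <- sex_table$sex[match(cats$sample_ids, sex_table$sample)]
  if (anyNA(sex)) stopf("sample(s) missing from the sex table")
  cM <- cats$categories[, sex == "M", drop = FALSE]
  cF <- cats$categories[, sex == "F", drop = FALSE]
  nM <- ncol(cM); nF <- ncol(cF)
  nw <- nrow(cats$categories)
  flag <- rep("none", nw)
  if (mode == "strict") {
    male_spec <- rowSums(cM == 2L) == nM & rowSums(cF == 0L) == nF
    female_spec <- rowSums(cF == 2L) == nF & rowSums(cM == 0L) == nM
    flag[male_spec] <- "male_specific"
    flag[female_spec] <- "female_specific"
    return(data.frame(flag = flag, p = NA_real_, stringsAsFactors = FALSE))
  }
  pres_M <- rowSums(cM >= 1L); pres_F <- rowSums(cF >= 1L)
  key <- paste(pres_F, pres_M)
  u <- !duplicated(key)
  pu <- fisher2_p(pres_F[u], rep(nF, sum(u)), rep(nM, sum(u)),
                  (pres_F + pres_M)[u])
  p <- unname(pu[match(key, key[u])])
  cutoff <- bonferroni_cutoff(alpha, nw)
  male_spec <- p <= cutoff &
    pres_M / nM >= min_present_fraction & pres_F / nF <= max_absent_leak
  female_spec <- p <= cutoff &
    pres_F / nF >= min_present_fraction & pres_M / nM <= max_absent_leak
  flag[male_spec] <- "male_specific"
  flag[female_spec] <- "female_specific"
  data.frame(flag = flag, p = p, stringsAsFactors = FALSE)
}

#' Merge flagged windows into candidate sex-specific regions
#'
#' Maximal runs of same-specificity flagged windows on a chromosome,
#' allowing up to `max_gap_windows` unflagged windows inside a run, are
#' reported as regions when they contain at least `min_windows` flagged
#' windows; region coordinates are the union span of the flagged windows.
#'
#' @param flags data.frame from [window_sex_match()] (or a character
#'   vector of flags) aligned to `grid`.
#' @param grid the window grid the flags refer to.
#' @param max_gap_windows unflagged windows tolerated inside a run.
#' @param min_windows minimum flagged windows per reported region.
#' @param cats optional `category_matrix` used to annotate each region
#'   with its worst-window presence fraction and absence leak.
#' @param sex_table required when `cats` is given.
#' @return data.frame of regions: chrom, start, end, specificity,
#'   n_windows, neg_log10_p, min_present_fraction, max_absent_leak;
#'   intervals are disjoint and sorted.
#' @export
merge_regions <- function(flags, grid, max_gap_windows = 0L,
                          min_windows = 1L, cats = NULL, sex_table = NULL) {
  fl <- if (is.data.frame(flags)) flags$flag else flags
  pv <- if (is.data.frame(flags) && "p" %in% names(flags)) flags$p else
    rep(NA_real_, length(fl))
  stopifnot(length(fl) == nrow(grid))
  regions <- list()
  for (chrom in unique(grid$chrom)) {
    ci <- which(grid$chrom == chrom)
    for (spec in c("male_specific", "female_specific")) {
      hit <- which(fl[ci] == spec)
      if (!length(hit)) next
      grp <- cumsum(c(1L, diff(hit) > max_gap_windows + 1L))
      for (g in split(hit, grp)) {
        if (length(g) < min_windows) next
        w <- ci[g]
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = chrom,
          start = grid$start[w[1]], end = grid$end[w[length(w)]],
          specificity = spec, n_windows = length(g),
          neg_log10_p = if (all(is.na(pv[w]))) NA_real_ else
            min(999, -log10(max(min(pv[w], na.rm = TRUE), 1e-300))),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               specificity = character(0), n_windows = integer(0),
               neg_log10_p = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(grid$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$min_present_fraction <- rep(NA_real_, nrow(out))
  out$max_absent_leak <- rep(NA_real_, nrow(out))
  if (!is.null(cats) && nrow(out)) {
    sex <- sex_table$sex[match(cats$sample_ids, sex_table$sample)]
    for (i in seq_len(nrow(out))) {
      w <- which(grid$chrom == out$chrom[i] & grid$start >= out$start[i] &
                   grid$end <= out$end[i])
      pres_sex <- if (out$specificity[i] == "male_specific") "M" else "F"
      cp <- cats$categories[w, sex == pres_sex, drop = FALSE]
      ca <- cats$categories[w, sex != pres_sex, drop = FALSE]
      out$min_present_fraction[i] <- min(rowMeans(cp == 2L))
      out$max_absent_leak[i] <- max(rowMeans(ca >= 1L))
    }
  }
  out
}

#' Refine region boundaries with a presence/absence criterion
#'
#' The strict per-window test (every presence-sex sample at category 2)
#' loses boundary windows to Poisson sampling noise: at hemizygous depth
#' `mean_depth/2`, a window occasionally drops below 3 reads in one
#' sample.  This step extends each region outwards while every
#' presence-sex sample retains at least one read and every absence-sex
#' sample has none, then merges regions that become adjacent or
#' overlapping.  It recovers boundary windows and bridges interior
#' dropouts without ever crossing into diploid sequence, where the
#' absence sex essentially always has reads.
#'
#' @param regions data.frame from [merge_regions()].
#' @param cats the `category_matrix` the regions were called from.
#' @param sex_table data.frame of sample, sex.
#' @param grid the window grid.
#' @return the refined regions data.frame.
#' @export
refine_region_boundaries <- function(regions, cats, sex_table, grid) {
  if (!nrow(regions)) return(regions)
  sex <- sex_table$sex[match(cats$sample_ids, sex_table$sample)]
  ok_window <- function(w, pres_sex) {
    cp <- cats$categories[w, sex == pres_sex]
    ca <- cats$categories[w, sex != pres_sex]
    all(cp >= 1L) && all(ca == 0L)
  }
  for (i in seq_len(nrow(regions))) {
    ci <- which(grid$chrom == regions$chrom[i])
    pres_sex <- if (regions$specificity[i] == "male_specific") "M" else "F"
    first <- ci[match(TRUE, grid$start[ci] >= regions$start[i])]
    last <- ci[max(which(grid$end[ci] <= regions$end[i]))]
    w <- first - 1L
    while (w >= ci[1] && grid$chrom[w] == regions$chrom[i] &&
           ok_window(w, pres_sex)) { first <- w; w <- w - 1L }
    w <- last + 1L
    while (w <= ci[length(ci)] && grid$chrom[w] == regions$chrom[i] &&
           ok_window(w, pres_sex)) { last <- w; w <- w + 1L }
    regions$start[i] <- grid$start[first]
    regions$end[i] <- grid$end[last]
  }
  # merge overlapping/adjacent same-specificity regions
  o <- order(match(regions$chrom, unique(grid$chrom)), regions$start)
  regions <- regions[o, , drop = FALSE]
  keep <- logical(nrow(regions))
  j <- 0L
  for (i in seq_len(nrow(regions))) {
    if (j > 0L && regions$chrom[i] == regions$chrom[j] &&
        regions$specificity[i] == regions$specificity[j] &&
        regions$start[i] <= regions$end[j]) {
      regions$end[j] <- max(regions$end[j], regions$end[i])
      regions$n_windows[j] <- regions$n_windows[j] + regions$n_windows[i]
      ps <- c(regions$neg_log10_p[j], regions$neg_log10_p[i])
      regions$neg_log10_p[j] <- if (all(is.na(ps))) NA_real_ else
        max(ps, na.rm = TRUE)
    } else { j <- i; keep[i] <- TRUE }
  }
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call sex-specific regions from a coverage matrix
#'
#' Convenience wrapper: categorise depths, flag windows, merge runs, and
#' (for the strict mode) refine boundaries with the presence/absence
#' criterion.
#'
#' @param cov a [coverage_matrix()].
#' @param sex_table data.frame of sample, sex.
#' @param mode `"strict"` or `"relaxed"` (see [window_sex_match()]).
#' @param max_gap_windows,min_windows see [merge_regions()].
#' @param refine extend strict-region boundaries over sampling dropouts
#'   (default TRUE in strict mode).
#' @param ... further arguments passed to [window_sex_match()].
#' @return data.frame of regions.
#' @export
call_sex_regions <- function(cov, sex_table, mode = c("strict", "relaxed"),
                             max_gap_windows = 2L, min_windows = 1L,
                             refine = TRUE, ...) {
  mode <- match.arg(mode)
  cats <- categorize_depth(cov)
  flags <- window_sex_match(cats, sex_table, mode = mode, ...)
  regions <- merge_regions(flags, cov$grid, max_gap_windows = max_gap_windows,
                           min_windows = min_windows, cats = cats,
                           sex_table = sex_table)
  if (mode == "strict" && refine)
    regions <- refine_region_boundaries(regions, cats, sex_table, cov$grid)
  regions
}

#' Compare region calls made under two references
#'
#' Pairs regions from the female-reference run and the Y-substituted-
#' reference run by positional overlap and labels each as
#' reference-independent (an overlapping counterpart exists) or
#' reference-dependent.  A planted hemizygous interval is only
#' *representable* in the reference that contains the hemizygous
#' sequence: under the female reference no windows exist over a YHS, so
#' such truth intervals are reported as detectable only in the
#' Y-substituted system.
#'
#' @param regions_female regions called under the female reference.
#' @param regions_y regions called under the Y-substituted reference.
#' @param samples_female,samples_y the sample ids used in each run (must
#'   match).
#' @param truth_yhs optional truth data.frame (name, chrom, start, end in
#'   Y-reference coordinates) of planted hemizygous intervals.
#' @return list with `regions` (all regions, annotated with `reference`
#'   and `status`) and, when truth is given, `truth_detectability`.
#' @export
compare_references <- function(regions_female, regions_y,
                               samples_female = NULL, samples_y = NULL,
                               truth_yhs = NULL) {
  if (!is.null(samples_female) && !is.null(samples_y) &&
      !setequal(samples_female, samples_y))
    stopf("the two runs used different sample sets")
  tag <- function(df, ref) {
    if (!nrow(df)) return(cbind(df, reference = character(0),
                                status = character(0)))
    df$reference <- ref
    df
  }
  rf <- tag(regions_female, "female")
  ry <- tag(regions_y, "y_substituted")
  has_overlap <- function(a, b) {
    if (!nrow(b)) return(rep(FALSE, nrow(a)))
    vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] &
            interval_overlap(b$start, b$end, a$start[i], a$end[i]) > 0)
    }, TRUE)
  }
  if (nrow(rf)) rf$status <- ifelse(has_overlap(rf, ry),
                                    "reference_independent",
                                    "reference_dependent")
  if (nrow(ry)) ry$status <- ifelse(has_overlap(ry, rf),
                                    "reference_independent",
                                    "reference_dependent")
  out <- list(regions = rbind(rf, ry))
  if (!is.null(truth_yhs) && nrow(truth_yhs)) {
    det_y <- vapply(seq_len(nrow(truth_yhs)), function(i) {
      any(regions_y$chrom == truth_yhs$chrom[i] &
            interval_overlap(regions_y$start, regions_y$end,
                             truth_yhs$start[i], truth_yhs$end[i]) > 0)
    }, TRUE)
    out$truth_detectability <- data.frame(
      name = truth_yhs$name,
      representable_in_female_reference = FALSE,
      detected_in_y_reference = det_y,
      stringsAsFactors = FALSE)
  }
  out
}

#' In-silico presence confirmation of regions in hold-out samples
#'
#' The computational analogue of confirming a candidate male-specific
#' region by PCR in an independent panel: a sample is scored as carrying
#' the region when any window inside it reaches category 2.  Returns the
#' confusion of presence against sex, per region, and flags discordant
#' samples rather than absorbing them.
#'
#' @param regions data.frame of regions (chrom, start, end, specificity).
#' @param cov hold-out [coverage_matrix()] on the same reference.
#' @param sex_table data.frame of sample, sex for the hold-out samples.
#' @return data.frame with one row per region x sample: region name,
#'   sample, sex, present, concordant.
#' @export
check_region_presence <- function(regions, cov, sex_table) {
  stopifnot(inherits(cov, "coverage_matrix"))
  cats <- categorize_depth(cov)
  sex <- sex_table$sex[match(cov$sample_ids, sex_table$sample)]
  if (anyNA(sex)) stopf("sample(s) missing from the sex table")
  out <- list()
  for (i in seq_len(nrow(regions))) {
    w <- which(cov$grid$chrom == regions$chrom[i] &
                 cov$grid$start < regions$end[i] &
                 cov$grid$end > regions$start[i])
    if (!length(w)) stopf("region %d lies outside the coverage grid", i)
    present <- colSums(cats$categories[w, , drop = FALSE] == 2L) > 0L
    pres_sex <- if (regions$specificity[i] == "male_specific") "M" else "F"
    out[[i]] <- data.frame(
      region = sprintf("%s:%d-%d", regions$chrom[i], regions$start[i],
                       regions$end[i]),
      sample = cov$sample_ids, sex = sex, present = unname(present),
      concordant = unname(present == (sex == pres_sex)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
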