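#' Construct a genotype matrix
#'
#' Container for biallelic SNP calls: a sites table (chrom, 0-based pos0,
#' ref, alt) and an integer matrix of genotype codes (rows = sites,
#' columns = samples) with 0 = hom ref, 1 = het, 2 = hom alt, NA = missing.
#'
#' @param sites data.frame with columns chrom, pos0, ref, alt.
#' @param geno integer matrix, `nrow(sites)` x `length(sample_ids)`.
#' @param sample_ids character vector of sample names.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, sample_ids) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos0", "ref", "alt") %in% names(sites)),
            nrow(sites) == nrow(geno), ncol(geno) == length(sample_ids))
  if (anyDuplicated(sites[c("chrom", "pos0")]))
    stopf("duplicate sites in genotype matrix")
  geno <- matrix(as.integer(geno), nrow(geno), ncol(geno))
  colnames(geno) <- sample_ids
  structure(list(sites = sites, geno = geno, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNP sites x %d samples\n",
              nrow(x$sites), length(x$sample_ids)))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  chromosomes: %s; missing calls: %.2f%%\n",
              paste(unique(x$sites$chrom), collapse = ", "), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Read a sex-phenotype table
#'
#' Two-column whitespace/tab-separated file `sample sex` with sex in
#' \{F, M\}; a header line is detected and skipped.
#'
#' @param path file path.
#' @return data.frame with columns `sample` and `sex`.
#' @export
read_sex_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("sample", "sex"))
  if (nrow(df) && tolower(df$sex[1]) %in% c("sex"))
    df <- df[-1, , drop = FALSE]
  if (!all(df$sex %in% c("F", "M")))
    stopf("sex must be 'F' or 'M'")
  if (anyDuplicated(df$sample)) stopf("duplicate sample ids in sex table")
  if (length(unique(df$sex)) < 2L)
    stopf("need at least one sample of each sex")
  rownames(df) <- NULL
  df
}

#' Read population genotypes from a VCF
#'
#' Parses a VCFv4.2 file (GT field), keeping only biallelic SNP records;
#' dropped records are reported via a message.  POS is converted to
#' 0-based coordinates internally.  Unparsable GT values become missing
#' with a warning; a VCF sample absent from the sex table is an error.
#'
#' @param vcf_path path to a VCF file.
#' @param sex_table data.frame as returned by [read_sex_table()].
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_path, sex_table) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("read_genotypes: dropped %d non-biallelic/non-SNP records",
                    n_drop))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  missing_ids <- setdiff(samples, sex_table$sample)
  if (length(missing_ids))
    stopf("VCF sample(s) absent from the sex table: %s",
          paste(missing_ids, collapse = ", "))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gtc <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gtc), ncol(gtc))
  code[gtc == "0/0"] <- 0L
  code[gtc %in% c("0/1", "1/0")] <- 1L
  code[gtc == "1/1"] <- 2L
  unparsable <- !is.na(gtc) & is.na(code) &
    !(gtc %in% c("./.", ".", ".|."))
  if (any(unparsable)) {
    warning(sprintf("%d unparsable GT value(s) set to missing",
                    sum(unparsable)), call. = FALSE)
  }
  sites <- data.frame(chrom = fix$CHROM,
                      pos0 = as.integer(fix$POS) - 1L,
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  o <- order(match(sites$chrom, unique(sites$chrom)), sites$pos0)
  genotype_matrix(sites[o, , drop = FALSE], code[o, , drop = FALSE], samples)
}

#' Write a genotype matrix as a plain-text VCFv4.2 file
#'
#' Minimal biallelic GT-only records with 1-based POS.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  gt[!is.na(gm$geno) & gm$geno == 0L] <- "0/0"
  gt[!is.na(gm$geno) & gm$geno == 1L] <- "0/1"
  gt[!is.na(gm$geno) & gm$geno == 2L] <- "1/1"
  body <- paste(gm$sites$chrom, gm$sites$pos0 + 1L, ".",
                gm$sites$ref, gm$sites$alt, ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter sites on minor-allele frequency and missingness
#'
#' Mirrors the conventional population screen (plink's `--maf 0.05
#' --geno 0.1`): a site is kept when its minor-allele frequency, computed
#' from genotype-derived allele counts over non-missing calls, is at least
#' `maf_min`, and its missing fraction is at most `max_missing`.  No HWE
#' assumption is made (fully sex-linked sites violate HWE by
#' construction).  Site order is preserved; the operation is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param max_missing maximum fraction of missing calls (default 0.1).
#' @return the filtered [genotype_matrix()].
#' @export
filter_sites <- function(gm, maf_min = 0.05, max_missing = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  n_called <- rowSums(!is.na(g))
  miss_frac <- 1 - n_called / ncol(g)
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), 0)
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & miss_frac <= max_missing & n_called > 0
  if (!any(keep))
    warning("all sites removed by filtering", call. = FALSE)
  genotype_matrix(gm$sites[keep, , drop = FALSE],
                  g[keep, , drop = FALSE], gm$sample_ids)
}

#' Classify sex-exactly-matching SNPs (SEMS)
#'
#' A site matches the XY pattern when every non-missing female is
#' homozygous and every non-missing male is heterozygous, and each sex's
#' call rate at the site is at least `min_callrate_per_sex`; the ZW
#' pattern is the mirror image.  A site can match at most one pattern.
#' By default a mix of hom-ref and hom-alt across the homozygous sex is
#' allowed (each individual is constrained, not the population);
#' `strict_hom_class = TRUE` additionally requires a single homozygous
#' class.  `strict_missing = TRUE` requires zero missing calls.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param sex_table data.frame of sample, sex covering all samples.
#' @param patterns subset of `c("XY", "ZW")` to consider.
#' @param min_callrate_per_sex minimum per-sex call rate (default 0.9).
#' @param strict_hom_class require a single homozygous class.
#' @param strict_missing require complete data at the site.
#' @param slr_interval optional `list(chrom =, start =, end =)` declaring
#'   the SLR; fills the `in_slr` flag.
#' @return data.frame of SEMS records: site index, chrom, pos0, ref, alt,
#'   pattern, conforming and missing counts per sex, `in_slr`, and the
#'   two-sided exact association p-value `p_exact`.
#' @export
classify_sems <- function(gm, sex_table, patterns = c("XY", "ZW"),
                          min_callrate_per_sex = 0.9,
                          strict_hom_class = FALSE,
                          strict_missing = FALSE,
                          slr_interval = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  patterns <- match.arg(patterns, several.ok = TRUE)
  sex <- sex_table$sex[match(gm$sample_ids, sex_table$sample)]
  if (anyNA(sex)) stopf("sample(s) missing from the sex table")
  gF <- gm$geno[, sex == "F", drop = FALSE]
  gM <- gm$geno[, sex == "M", drop = FALSE]
  nF <- ncol(gF); nM <- ncol(gM)
  if (nF == 0L || nM == 0L) stopf("need both sexes")

  miss_F <- rowSums(is.na(gF)); miss_M <- rowSums(is.na(gM))
  call_F <- nF - miss_F; call_M <- nM - miss_M
  het_F <- rowSums(gF == 1L, na.rm = TRUE)
  het_M <- rowSums(gM == 1L, na.rm = TRUE)
  hom_F <- call_F - het_F
  hom_M <- call_M - het_M
  homref_F <- rowSums(gF == 0L, na.rm = TRUE)
  homalt_F <- rowSums(gF == 2L, na.rm = TRUE)
  homref_M <- rowSums(gM == 0L, na.rm = TRUE)
  homalt_M <- rowSums(gM == 2L, na.rm = TRUE)

  rate_ok <- call_F >= min_callrate_per_sex * nF &
    call_M >= min_callrate_per_sex * nM & call_F > 0L & call_M > 0L
  if (strict_missing) rate_ok <- rate_ok & miss_F == 0L & miss_M == 0L

  one_class_F <- homref_F == hom_F | homalt_F == hom_F
  one_class_M <- homref_M == hom_M | homalt_M == hom_M
  xy <- rate_ok & het_F == 0L & hom_F == call_F & het_M == call_M
  zw <- rate_ok & het_M == 0L & hom_M == call_M & het_F == call_F
  if (strict_hom_class) { xy <- xy & one_class_F; zw <- zw & one_class_M }
  if (!"XY" %in% patterns) xy[] <- FALSE
  if (!"ZW" %in% patterns) zw[] <- FALSE

  idx <- which(xy | zw)
  if (!length(idx)) {
    return(data.frame(site = integer(0), chrom = character(0),
                      pos0 = integer(0), ref = character(0),
                      alt = character(0), pattern = character(0),
                      n_conf_f = integer(0), n_conf_m = integer(0),
                      n_missing_f = integer(0), n_missing_m = integer(0),
                      in_slr = logical(0), p_exact = numeric(0)))
  }
  pattern <- ifelse(xy[idx], "XY", "ZW")
  p <- exact_association(gm, sex_table)[idx]
  in_slr <- rep(NA, length(idx))
  if (!is.null(slr_interval)) {
    in_slr <- gm$sites$chrom[idx] == slr_interval$chrom &
      gm$sites$pos0[idx] >= slr_interval$start &
      gm$sites$pos0[idx] < slr_interval$end
  }
  data.frame(site = idx,
             chrom = gm$sites$chrom[idx], pos0 = gm$sites$pos0[idx],
             ref = gm$sites$ref[idx], alt = gm$sites$alt[idx],
             pattern = pattern,
             n_conf_f = ifelse(pattern == "XY", hom_F[idx], het_F[idx]),
             n_conf_m = ifelse(pattern == "XY", het_M[idx], hom_M[idx]),
             n_missing_f = miss_F[idx], n_missing_m = miss_M[idx],
             in_slr = in_slr, p_exact = p,
             stringsAsFactors = FALSE)
}

# two-sided Fisher exact p for a 2x2 table given as vectors:
# x = female carriers, K = total carriers, over nF females / nM males.
fisher2_p <- function(x, call_F, call_M, K) {
  n <- length(x)
  p <- numeric(n)
  for (i in seq_len(n)) {
    if (K[i] == 0L || K[i] == call_F[i] + call_M[i] ||
        call_F[i] == 0L || call_M[i] == 0L) { p[i] <- 1; next }
    supp <- max(0L, K[i] - call_M[i]):min(K[i], call_F[i])
    d <- dhyper(supp, call_F[i], call_M[i], K[i])
    p[i] <- min(1, sum(d[d <= d[supp == x[i]] * (1 + 1e-7)]))
  }
  p
}

#' Per-site exact association between heterozygosity and sex
#'
#' For each site, builds the 2x2 table (heterozygote carrier vs
#' non-carrier) x (female vs male) over non-missing calls and returns the
#' two-sided Fisher exact p-value (the sum of hypergeometric probabilities
#' not exceeding that of the observed table).  This exact test is the
#' association scan of the pipeline: under perfect genotype-sex separation
#' it attains the minimum possible p for the sample split, so the ranking
#' it induces agrees with any association statistic maximal at perfect
#' separation.  Degenerate tables (a zero margin) yield p = 1.
#'
#' @param gm a [genotype_matrix()].
#' @param sex_table data.frame of sample, sex.
#' @return numeric vector of per-site two-sided p-values.
#' @export
exact_association <- function(gm, sex_table) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sex <- sex_table$sex[match(gm$sample_ids, sex_table$sample)]
  if (anyNA(sex)) stopf("sample(s) missing from the sex table")
  gF <- gm$geno[, sex == "F", drop = FALSE]
  gM <- gm$geno[, sex == "M", drop = FALSE]
  call_F <- rowSums(!is.na(gF)); call_M <- rowSums(!is.na(gM))
  het_F <- rowSums(gF == 1L, na.rm = TRUE)
  het_M <- rowSums(gM == 1L, na.rm = TRUE)
  K <- het_F + het_M
  # tables recur massively across sites; compute unique ones once
  key <- paste(het_F, call_F, call_M, K)
  u <- !duplicated(key)
  pu <- fisher2_p(het_F[u], call_F[u], call_M[u], K[u])
  unname(pu[match(key, key[u])])
}

#' Bonferroni significance cutoff
#'
#' @param alpha family-wise significance level in (0, 1].
#' @param n_tests number of tests (>= 1).
#' @return the per-test p-value cutoff `alpha / n_tests`.
#' @export
bonferroni_cutoff <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must lie in (0, 1]")
  if (n_tests < 1) stopf("n_tests must be >= 1")
  alpha / n_tests
}

#' Infer heterogamety from SEMS records
#'
#' Calls XY (male heterogamety) or ZW (female heterogamety) when the
#' majority pattern among SEMS records exceeds the declared ratio over the
#' minority; otherwise `undetermined`.
#'
#' @param sems data.frame of SEMS records from [classify_sems()].
#' @param ratio required majority:minority ratio (default 2).
#' @return list with `call` in \{"XY", "ZW", "undetermined"\} and the
#'   supporting counts `n_xy`, `n_zw`.
#' @export
infer_heterogamety <- function(sems, ratio = 2) {
  n_xy <- sum(sems$pattern == "XY")
  n_zw <- sum(sems$pattern == "ZW")
  call <- "undetermined"
  if (n_xy + n_zw > 0L) {
    if (n_xy > ratio * n_zw) call <- "XY"
    else if (n_zw > ratio * n_xy) call <- "ZW"
  }
  list(call = call, n_xy = n_xy, n_zw = n_zw)
}
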