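#' Dual-reference sex-linked-region analysis
#'
#' The orchestrating analysis: under each reference (female and
#' Y-substituted) it filters sites, classifies SEMS, and scans windowed
#' coverage for sex-specific regions; it then intersects the two SEMS
#' lists by position (positions outside the SLR are identical under both
#' references by construction), labels the SEMS found only under the
#' female reference as *eliminated* — the signature of cross-mapping
#' false positives — and, when the reference sequences are supplied,
#' attaches the sequence-similarity cross-mapping flag to every non-SLR
#' SEMS.  Fully deterministic given its inputs.
#'
#' @param geno_female,geno_y [genotype_matrix()] objects called against
#'   the female and Y-substituted references.
#' @param cov_female,cov_y matching [coverage_matrix()] objects.
#' @param sex_table data.frame of sample, sex.
#' @param slr_interval `list(chrom =, start =, end =)`: the declared SLR
#'   in female-reference coordinates (SLR delimitation comes from linkage
#'   mapping and is an input, not re-estimated).
#' @param slr_interval_y the declared SLR in Y-substituted coordinates
#'   (wider by the total hemizygous insertion length).
#' @param female_reference optional named vector of chromosome sequences;
#'   enables the cross-mapping similarity flag.
#' @param slr_y_sequence optional Y haplotype sequence of the SLR.
#' @param maf_min,max_missing site filters (defaults 0.05 / 0.1).
#' @param min_callrate_per_sex,strict_hom_class,strict_missing SEMS
#'   options, see [classify_sems()].
#' @param region_mode `"strict"` or `"relaxed"` coverage scan mode.
#' @param alpha significance level for the relaxed scan.
#' @param max_gap_windows gap tolerance when merging flagged windows.
#' @param crossmap_flank,crossmap_min_identity cross-mapping screen
#'   parameters, see [flag_crossmap_sems()].
#' @return an object of class `slr_report`: SEMS tables under both
#'   references, eliminated SEMS, region calls and per-site Manhattan
#'   tables (chrom, pos0, -log10 exact p) under both references, the
#'   heterogamety call, summary counts, and the thresholds used.
#' @export
dual_reference_analysis <- function(geno_female, cov_female,
                                    geno_y, cov_y, sex_table,
                                    slr_interval, slr_interval_y,
                                    female_reference = NULL,
                                    slr_y_sequence = NULL,
                                    maf_min = 0.05, max_missing = 0.1,
                                    min_callrate_per_sex = 0.9,
                                    strict_hom_class = FALSE,
                                    strict_missing = FALSE,
                                    region_mode = c("strict", "relaxed"),
                                    alpha = 0.01,
                                    max_gap_windows = 2L,
                                    crossmap_flank = 500L,
                                    crossmap_min_identity = 0.9) {
  region_mode <- match.arg(region_mode)
  if (!setequal(geno_female$sample_ids, geno_y$sample_ids))
    stopf("sample sets differ between the two references")
  thresholds <- list(maf_min = maf_min, max_missing = max_missing,
                     min_callrate_per_sex = min_callrate_per_sex,
                     strict_hom_class = strict_hom_class,
                     strict_missing = strict_missing,
                     region_mode = region_mode, alpha = alpha,
                     max_gap_windows = max_gap_windows,
                     crossmap_flank = crossmap_flank,
                     crossmap_min_identity = crossmap_min_identity)

  scan_one <- function(geno, cov, slr_iv) {
    filt <- filter_sites(geno, maf_min = maf_min, max_missing = max_missing)
    sems <- classify_sems(filt, sex_table,
                          min_callrate_per_sex = min_callrate_per_sex,
                          strict_hom_class = strict_hom_class,
                          strict_missing = strict_missing,
                          slr_interval = slr_iv)
    p <- exact_association(filt, sex_table)
    manhattan <- data.frame(chrom = filt$sites$chrom,
                            pos0 = filt$sites$pos0,
                            neg_log10_p = pmin(999, -log10(pmax(p, 1e-300))),
                            stringsAsFactors = FALSE)
    regions <- call_sex_regions(cov, sex_table, mode = region_mode,
                                max_gap_windows = max_gap_windows,
                                alpha = alpha)
    list(sems = sems, regions = regions, manhattan = manhattan,
         n_sites = nrow(filt$sites))
  }
  f <- scan_one(geno_female, cov_female, slr_interval)
  y <- scan_one(geno_y, cov_y, slr_interval_y)

  key <- function(s) paste(s$chrom, s$pos0)
  nonslr_f <- f$sems[!f$sems$in_slr, , drop = FALSE]
  nonslr_y <- y$sems[!y$sems$in_slr, , drop = FALSE]
  eliminated <- nonslr_f[!key(nonslr_f) %in% key(nonslr_y), , drop = FALSE]

  sems_f <- f$sems
  if (!is.null(female_reference) && !is.null(slr_y_sequence)) {
    sems_f <- flag_crossmap_sems(sems_f, female_reference, slr_y_sequence,
                                 flank = crossmap_flank,
                                 min_identity = crossmap_min_identity)
    eliminated <- sems_f[!sems_f$in_slr &
                           key(sems_f) %in% key(eliminated), , drop = FALSE]
  }

  het <- infer_heterogamety(rbind(f$sems, y$sems))
  counts <- list(
    female = c(total = nrow(f$sems), in_slr = sum(f$sems$in_slr),
               non_slr = sum(!f$sems$in_slr)),
    y_substituted = c(total = nrow(y$sems), in_slr = sum(y$sems$in_slr),
                      non_slr = sum(!y$sems$in_slr)),
    eliminated = nrow(eliminated),
    crossmap_suspect = if ("crossmap_suspect" %in% names(sems_f))
      sum(sems_f$crossmap_suspect, na.rm = TRUE) else NA_integer_)

  structure(list(sems_female = sems_f, sems_y = y$sems,
                 eliminated = eliminated,
                 regions_female = f$regions, regions_y = y$regions,
                 manhattan_female = f$manhattan, manhattan_y = y$manhattan,
                 heterogamety = het, counts = counts,
                 thresholds = thresholds,
                 slr_interval = slr_interval,
                 slr_interval_y = slr_interval_y),
            class = "slr_report")
}

#' @export
print.slr_report <- function(x, ...) {
  cat("Dual-reference sex-linked-region analysis\n")
  cat(sprintf("  heterogamety: %s (XY-pattern SEMS: %d, ZW-pattern: %d)\n",
              x$heterogamety$call, x$heterogamety$n_xy, x$heterogamety$n_zw))
  cf <- x$counts$female; cy <- x$counts$y_substituted
  cat(sprintf("  SEMS under female reference:        %d (%d in SLR, %d outside)\n",
              cf["total"], cf["in_slr"], cf["non_slr"]))
  cat(sprintf("  SEMS under Y-substituted reference: %d (%d in SLR, %d outside)\n",
              cy["total"], cy["in_slr"], cy["non_slr"]))
  cat(sprintf("  eliminated by the reference swap:   %d", x$counts$eliminated))
  if (!is.na(x$counts$crossmap_suspect))
    cat(sprintf(" (cross-mapping suspects flagged: %d)",
                x$counts$crossmap_suspect))
  cat("\n")
  rsum <- function(r) if (!nrow(r)) "none" else
    paste(sprintf("%s:%d-%d (%s, %d bp)", r$chrom, r$start, r$end,
                  r$specificity, r$end - r$start), collapse = "; ")
  cat(sprintf("  sex-specific regions, female ref:   %s\n",
              rsum(x$regions_female)))
  cat(sprintf("  sex-specific regions, Y-sub ref:    %s\n",
              rsum(x$regions_y)))
  invisible(x)
}

#' File-based dual-reference run
#'
#' Reads the external artifacts (VCFs, coverage TSVs, sex table, FASTA
#' references), executes [dual_reference_analysis()], and writes the SEMS
#' tables (TSV, 1-based positions), region BEDs, Manhattan tables and a
#' JSON report under `outdir`.
#'
#' @param paths named list with elements `vcf_female`, `vcf_y`,
#'   `cov_female`, `cov_y`, `sex`, and optionally `female_fasta` and
#'   `y_fasta` (enables the cross-mapping screen).
#' @param slr_interval,slr_interval_y declared SLR intervals, see
#'   [dual_reference_analysis()].
#' @param outdir output directory.
#' @param ... further options passed to [dual_reference_analysis()].
#' @return the `slr_report`, invisibly.
#' @export
run_dual_reference <- function(paths, slr_interval, slr_interval_y,
                               outdir, ...) {
  need <- c("vcf_female", "vcf_y", "cov_female", "cov_y", "sex")
  for (p in need) {
    if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
      stopf("missing input: %s (%s)", p, paths[[p]] %||% "unset")
  }
  sex_table <- read_sex_table(paths$sex)
  geno_f <- read_genotypes(paths$vcf_female, sex_table)
  geno_y <- read_genotypes(paths$vcf_y, sex_table)
  cov_f <- read_coverage(paths$cov_female)
  cov_y <- read_coverage(paths$cov_y)
  female_ref <- NULL; slr_y_seq <- NULL
  if (!is.null(paths$female_fasta) && !is.null(paths$y_fasta)) {
    female_ref <- read_fasta(paths$female_fasta)
    y_ref <- read_fasta(paths$y_fasta)
    slr_y_seq <- substr(y_ref[[slr_interval_y$chrom]],
                        slr_interval_y$start + 1L, slr_interval_y$end)
  }
  report <- dual_reference_analysis(geno_f, cov_f, geno_y, cov_y, sex_table,
                                    slr_interval, slr_interval_y,
                                    female_reference = female_ref,
                                    slr_y_sequence = slr_y_seq, ...)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr_sems <- function(s, path) {
    out <- s
    out$pos <- out$pos0 + 1L
    out$pos0 <- NULL
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr_sems(report$sems_female, file.path(outdir, "sems_female_ref.tsv"))
  wr_sems(report$sems_y, file.path(outdir, "sems_y_ref.tsv"))
  wr_sems(report$eliminated, file.path(outdir, "sems_eliminated.tsv"))
  wr_manhattan <- function(m, path) {
    out <- data.frame(chrom = m$chrom, pos = m$pos0 + 1L,
                      neg_log10_p = m$neg_log10_p)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr_manhattan(report$manhattan_female,
               file.path(outdir, "manhattan_female_ref.tsv"))
  wr_manhattan(report$manhattan_y, file.path(outdir, "manhattan_y_ref.tsv"))
  write_regions_bed(report$regions_female,
                    file.path(outdir, "regions_female_ref.bed"))
  write_regions_bed(report$regions_y, file.path(outdir, "regions_y_ref.bed"))
  jsonlite::write_json(
    list(heterogamety = report$heterogamety,
         counts = report$counts, thresholds = report$thresholds,
         slr_interval = report$slr_interval,
         slr_interval_y = report$slr_interval_y,
         package_version = as.character(utils::packageVersion("slrscan"))),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}
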