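#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a coverage matrix as a long-format TSV
#'
#' Columns `chrom start end sample depth`, BED-style 0-based half-open
#' windows.
#'
#' @param cov a [coverage_matrix()].
#' @param path output path.
#' @export
write_coverage <- function(cov, path) {
  stopifnot(inherits(cov, "coverage_matrix"))
  n <- length(cov$sample_ids)
  long <- data.table::data.table(
    chrom = rep(cov$grid$chrom, n),
    start = rep(cov$grid$start, n),
    end = rep(cov$grid$end, n),
    sample = rep(cov$sample_ids, each = nrow(cov$grid)),
    depth = as.vector(cov$depth))
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}

#' Read a long-format coverage TSV into a coverage matrix
#' @param path TSV path with columns chrom, start, end, sample, depth.
#' @export
read_coverage <- function(path) {
  long <- data.table::fread(path)
  stopifnot(all(c("chrom", "start", "end", "sample", "depth") %in%
                  names(long)))
  samples <- unique(long$sample)
  key <- paste(long$chrom, long$start)
  grid <- unique(data.frame(chrom = long$chrom, start = long$start,
                            end = long$end, stringsAsFactors = FALSE))
  wkey <- paste(grid$chrom, grid$start)
  depth <- matrix(0L, nrow(grid), length(samples),
                  dimnames = list(NULL, samples))
  depth[cbind(match(key, wkey), match(long$sample, samples))] <- long$depth
  coverage_matrix(grid, depth, samples)
}

#' Write a sample-sex table as TSV
#' @param sex_table data.frame of sample, sex.
#' @param path output path.
#' @export
write_sex_table <- function(sex_table, path) {
  utils::write.table(sex_table[c("sample", "sex")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write regions as a 6-column BED file
#'
#' name = specificity, score = -log10 p capped at 999 (0 when no p is
#' available), strand = ".".
#'
#' @param regions regions data.frame from [merge_regions()].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (!nrow(regions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- ifelse(is.na(regions$neg_log10_p), 0,
                  round(pmin(regions$neg_log10_p, 999)))
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$specificity, score, rep(".", nrow(regions)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write generator ground truth as JSON
#' @param truth an `slr_truth` object.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  x <- truth[c("sex_of", "true_sems", "artifact_sites", "true_yhs",
               "x_haplotype", "y_haplotype", "slr_interval",
               "slr_interval_y", "mother_id", "son_id")]
  x$sex_of <- as.list(x$sex_of)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a complete simulated scenario to a directory
#'
#' Materialises both references (FASTA), both reference modes' genotypes
#' (VCF) and coverage (TSV), the sex table and the ground truth (JSON)
#' under `outdir`, using the external formats consumed by
#' [run_dual_reference()].
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
write_simulated_scenario <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  refs <- build_references(config)
  sim_f <- simulate_population(config, refs$truth, "female")
  sim_y <- simulate_population(config, refs$truth, "y_substituted")
  paths <- list(
    female_fasta = file.path(outdir, "reference_female.fa"),
    y_fasta = file.path(outdir, "reference_y_substituted.fa"),
    vcf_female = file.path(outdir, "genotypes_female_ref.vcf"),
    vcf_y = file.path(outdir, "genotypes_y_ref.vcf"),
    cov_female = file.path(outdir, "coverage_female_ref.tsv"),
    cov_y = file.path(outdir, "coverage_y_ref.tsv"),
    sex = file.path(outdir, "sex.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_fasta(refs$female_reference, paths$female_fasta)
  write_fasta(refs$y_substituted_reference, paths$y_fasta)
  write_vcf(sim_f$genotypes, paths$vcf_female)
  write_vcf(sim_y$genotypes, paths$vcf_y)
  write_coverage(sim_f$coverage, paths$cov_female)
  write_coverage(sim_y$coverage, paths$cov_y)
  write_sex_table(sim_f$sex, paths$sex)
  write_truth_json(refs$truth, paths$truth)
  invisible(paths)
}

#' Build a simulation config from a YAML or JSON file
#'
#' The file holds any subset of [sim_config()]'s arguments under the same
#' names; unspecified fields keep their defaults.  Interval fields follow
#' the same conventions (`yhs_intervals` a named list of two-element
#' vectors; `paralog_map` a list of source/target_chrom/target/identity
#' entries).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param seed optional seed overriding the file's value.
#' @return a [sim_config()].
#' @export
sim_config_from_file <- function(path, seed = NULL) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$chrom_lengths))
    raw$chrom_lengths <- unlist(raw$chrom_lengths)
  if (!is.null(raw$yhs_intervals))
    raw$yhs_intervals <- lapply(raw$yhs_intervals, function(iv)
      as.integer(unlist(iv)))
  if (!is.null(raw$paralog_map))
    raw$paralog_map <- lapply(raw$paralog_map, function(p) {
      p$source <- as.integer(unlist(p$source))
      p$target <- as.integer(unlist(p$target))
      p
    })
  if (!is.null(seed)) raw$seed <- seed
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

#' Read per-sample bedGraph coverage tracks into a coverage matrix
#'
#' Each file holds `chrom start end depth` rows on a shared window grid;
#' the sample name is taken from the file name (without extension) unless
#' `sample_ids` is given.
#'
#' @param paths character vector of bedGraph paths.
#' @param sample_ids optional sample names matching `paths`.
#' @return a [coverage_matrix()].
#' @export
read_coverage_bedgraphs <- function(paths, sample_ids = NULL) {
  if (!length(paths)) stopf("no bedGraph files given")
  ids <- sample_ids %||% sub("\\.[^.]*$", "", basename(paths))
  first <- data.table::fread(paths[1],
                             col.names = c("chrom", "start", "end", "depth"))
  grid <- data.frame(chrom = first$chrom, start = first$start,
                     end = first$end, stringsAsFactors = FALSE)
  depth <- matrix(0L, nrow(grid), length(paths))
  depth[, 1] <- first$depth
  for (j in seq_along(paths)[-1]) {
    d <- data.table::fread(paths[j],
                           col.names = c("chrom", "start", "end", "depth"))
    if (nrow(d) != nrow(grid) || !all(d$chrom == grid$chrom &
                                        d$start == grid$start))
      stopf("bedGraph %s is not on the shared window grid", paths[j])
    depth[, j] <- d$depth
  }
  coverage_matrix(grid, depth, ids)
}

#' Assemble a trio phasing input from a VCF
#'
#' Restricts a VCF to the declared SLR and extracts the mother's and
#' son's genotype codes over the shared biallelic SNP sites.
#'
#' @param vcf_path VCF with GT calls including both trio members.
#' @param mother_id,son_id sample names in the VCF.
#' @param slr_interval `list(chrom =, start =, end =)`, 0-based half-open.
#' @return a trio input list accepted by [phase_slr()].
#' @export
read_trio <- function(vcf_path, mother_id, son_id, slr_interval) {
  # accept any samples in the VCF; only the two trio members are used
  header <- grep("^#CHROM", readLines(vcf_path, n = 1000L), value = TRUE)
  vcf_samples <- tail(strsplit(header[1], "\t")[[1]], -9L)
  sex <- data.frame(sample = vcf_samples,
                    sex = ifelse(vcf_samples == son_id, "M", "F"),
                    stringsAsFactors = FALSE)
  gm <- read_genotypes(vcf_path, sex)
  for (id in c(mother_id, son_id))
    if (!id %in% gm$sample_ids) stopf("sample %s not in the VCF", id)
  keep <- gm$sites$chrom == slr_interval$chrom &
    gm$sites$pos0 >= slr_interval$start & gm$sites$pos0 < slr_interval$end
  if (!any(keep)) stopf("no SLR sites in the VCF")
  list(sites = gm$sites[keep, , drop = FALSE],
       mother = unname(gm$geno[keep, mother_id]),
       son = unname(gm$geno[keep, son_id]),
       slr_interval = c(slr_interval$start, slr_interval$end))
}
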