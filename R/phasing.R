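#' Phase SLR-X and SLR-Y haplotypes from a mother-son pair
#'
#' In a non-recombining sex-linked region, a male's X haplotype is the
#' one he inherited from his mother, so her genotypes resolve the phase
#' of his heterozygous sites: where the son is heterozygous and the
#' mother homozygous, the mother's allele is the X allele and the other
#' is the Y allele.  Homozygous sites in the son phase trivially;
#' double-heterozygous sites are irreducibly ambiguous without read-backed
#' evidence and are reported as such, never guessed; a heterozygous son
#' carrying neither allele of a homozygous mother is a Mendelian
#' conflict, reported rather than dropped (a high conflict rate signals a
#' sample mix-up).
#'
#' @param trio a trio object as returned by [simulate_trio()], or any
#'   list with `sites` (data.frame chrom, pos0, ref, alt), `mother` and
#'   `son` genotype codes (0/1/2/NA) over the same sites, and
#'   `slr_interval`.
#' @return an object of class `phased_haplotypes`: the sites table with
#'   `x_allele`, `y_allele` and `status` in \{phased, ambiguous,
#'   mendel_conflict, missing\}, plus a printed summary of the conflict
#'   rate.
#' @export
phase_slr <- function(trio) {
  sites <- trio$sites
  if (is.null(sites) || nrow(sites) == 0L) stopf("empty site list")
  mother <- trio$mother; son <- trio$son
  stopifnot(length(mother) == nrow(sites), length(son) == nrow(sites))
  n <- nrow(sites)
  x_allele <- rep(NA_character_, n)
  y_allele <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  allele <- function(code_half, ref, alt) ifelse(code_half == 0L, ref, alt)
  for (i in seq_len(n)) {
    m <- mother[i]; s <- son[i]
    ref <- sites$ref[i]; alt <- sites$alt[i]
    if (is.na(m) || is.na(s)) { status[i] <- "missing"; next }
    if (s != 1L) {  # homozygous son: x = y = his allele
      # unless he shares no allele with a homozygous mother (mix-up signal)
      if (m != 1L && m != s) { status[i] <- "mendel_conflict"; next }
      a <- if (s == 0L) ref else alt
      x_allele[i] <- a; y_allele[i] <- a; status[i] <- "phased"
      next
    }
    if (m == 1L) { status[i] <- "ambiguous"; next }
    # het son with homozygous mother: her allele is the transmitted X
    m_allele <- if (m == 0L) ref else alt
    other <- if (m == 0L) alt else ref
    x_allele[i] <- m_allele; y_allele[i] <- other; status[i] <- "phased"
  }
  out <- cbind(sites,
               data.frame(x_allele = x_allele, y_allele = y_allele,
                          status = status, stringsAsFactors = FALSE))
  structure(list(table = out, slr_interval = trio$slr_interval,
                 conflict_rate = mean(status == "mendel_conflict")),
            class = "phased_haplotypes")
}

#' @export
print.phased_haplotypes <- function(x, ...) {
  tab <- table(factor(x$table$status,
                      levels = c("phased", "ambiguous", "mendel_conflict",
                                 "missing")))
  cat(sprintf("phased_haplotypes: %d SLR sites\n", nrow(x$table)))
  for (s in names(tab))
    cat(sprintf("  %-16s %d (%.1f%%)\n", s, tab[[s]],
                100 * tab[[s]] / nrow(x$table)))
  if (x$conflict_rate > 0.05)
    cat("  WARNING: high Mendelian conflict rate - check sample identities\n")
  invisible(x)
}

#' Emit phased SLR haplotypes as FASTA sequences
#'
#' Substitutes phased alleles into the SLR reference sequence to produce
#' the X and Y haplotype sequences.  Ambiguous sites become the IUPAC
#' two-base code of the son's alleles; conflict or missing sites become N.
#'
#' @param phased a `phased_haplotypes` object from [phase_slr()].
#' @param slr_reference the reference sequence of the SLR (the X-carrying
#'   reference restricted to `slr_interval`).
#' @param slr_offset 0-based genomic position of the first base of
#'   `slr_reference` (default: start of the stored `slr_interval`).
#' @return named character vector of two sequences, `SLR-X` and `SLR-Y`.
#' @export
emit_haplotype_fasta <- function(phased, slr_reference, slr_offset = NULL) {
  stopifnot(inherits(phased, "phased_haplotypes"))
  off <- slr_offset %||% phased$slr_interval[1]
  tab <- phased$table
  local <- tab$pos0 - off
  if (any(local < 0L | local >= nchar(slr_reference)))
    stopf("site outside the supplied SLR reference")
  refbase <- substring(slr_reference, local + 1L, local + 1L)
  bad <- toupper(refbase) != toupper(tab$ref)
  if (any(bad))
    stopf("reference allele mismatch at %d site(s); wrong reference or offset",
          sum(bad))
  xs <- strsplit(slr_reference, "", fixed = TRUE)[[1]]
  ys <- xs
  for (i in seq_len(nrow(tab))) {
    j <- local[i] + 1L
    if (tab$status[i] == "phased") {
      if (!all(c(tab$x_allele[i], tab$y_allele[i]) %in%
               c(tab$ref[i], tab$alt[i])))
        stopf("phased allele inconsistent with site ref/alt at row %d", i)
      xs[j] <- tab$x_allele[i]
      ys[j] <- tab$y_allele[i]
    } else if (tab$status[i] == "ambiguous") {
      code <- iupac_two(tab$ref[i], tab$alt[i])
      xs[j] <- code; ys[j] <- code
    } else {
      xs[j] <- "N"; ys[j] <- "N"
    }
  }
  c("SLR-X" = paste(xs, collapse = ""), "SLR-Y" = paste(ys, collapse = ""))
}
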