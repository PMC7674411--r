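# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: per-site loops, stats::fisher.test,
# Biostrings::pairwiseAlignment, and exhaustive enumeration.

# per-site SEMS pattern by direct inspection of one row of genotype codes
oracle_sems_site <- function(g, sex, min_callrate = 0.9,
                             strict_hom = FALSE, strict_missing = FALSE) {
  f <- g[sex == "F"]; m <- g[sex == "M"]
  fr <- f[!is.na(f)]; mr <- m[!is.na(m)]
  ok <- length(fr) >= min_callrate * length(f) &&
    length(mr) >= min_callrate * length(m) &&
    length(fr) > 0 && length(mr) > 0
  if (strict_missing) ok <- ok && !anyNA(f) && !anyNA(m)
  if (!ok) return("none")
  one_class <- function(x) length(unique(x)) <= 1L
  xy <- all(fr %in% c(0L, 2L)) && all(mr == 1L)
  zw <- all(mr %in% c(0L, 2L)) && all(fr == 1L)
  if (strict_hom) {
    xy <- xy && one_class(fr)
    zw <- zw && one_class(mr)
  }
  if (xy) "XY" else if (zw) "ZW" else "none"
}

oracle_sems <- function(geno, sex, ...) {
  vapply(seq_len(nrow(geno)), function(i) {
    oracle_sems_site(geno[i, ], sex, ...)
  }, "")
}

# two-sided Fisher exact p via stats::fisher.test on the 2x2 table
# (carrier x sex)
oracle_fisher <- function(het_f, het_m, nonhet_f, nonhet_m) {
  tab <- matrix(c(het_f, nonhet_f, het_m, nonhet_m), 2L)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) return(1)
  stats::fisher.test(tab)$p.value
}

# optimal local alignment score (linear gap) via Biostrings
oracle_sw_score <- function(q, t, match = 1, mismatch = -2, gap = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  max(0, Biostrings::pairwiseAlignment(q, t, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = gap,
                                       scoreOnly = TRUE))
}

# best local score over both strands
oracle_sw_score2 <- function(q, t, ...) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  max(oracle_sw_score(q, t, ...), oracle_sw_score(rc, t, ...))
}

# exhaustive maximum-score chain of hits non-overlapping on the query
oracle_best_chain <- function(qstart, qend, score, allowed_overlap = 10L) {
  n <- length(qstart)
  stopifnot(n <= 14L)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(sel)) next
    o <- sel[order(qstart[sel])]
    ok <- TRUE
    if (length(o) > 1L) {
      for (i in 2:length(o)) {
        if (qend[o[i - 1L]] > qstart[o[i]] + allowed_overlap) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, sum(score[sel]))
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# point-mutate a sequence at a fixed per-base rate
mutate_dna <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}
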