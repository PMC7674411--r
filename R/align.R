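#' Seed-and-extend local alignment
#'
#' Finds local alignments between two nucleotide sequences using exact
#' k-mer seeds on both strands, clustering of seed matches into diagonal
#' bands, and local dynamic-programming extension of each band (linear
#' gap penalty), with extension attempted up to `x_drop + k` bases past
#' the outermost seeds.  Overlapping hits are deduplicated; hits shorter
#' than `min_len` alignment columns or below `min_identity` are dropped.
#' Deterministic.  N bases never seed and always score as mismatches.
#'
#' @param query,target nucleotide sequences over \{A, C, G, T, N\}.
#' @param k seed length (>= 4; default 13).
#' @param min_len minimum alignment length in columns (default 50).
#' @param min_identity minimum matching fraction (default 0.8).
#' @param match,mismatch,gap scoring scheme (default +1 / -2 / -2).
#' @param x_drop extension allowance beyond the seeded band (default 20).
#' @return data.frame of local alignments with 0-based half-open `qstart`,
#'   `qend`, `tstart`, `tend`, `strand` (`-` means the reverse complement
#'   of the query aligns to the target), `identity`, `score`, `length`.
#' @export
seed_extend_align <- function(query, target, k = 13L, min_len = 50L,
                              min_identity = 0.8, match = 1L,
                              mismatch = -2L, gap = -2L, x_drop = 20L) {
  if (k < 4L) stopf("seed length k must be >= 4")
  if (k > min(nchar(query), nchar(target)))
    stopf("k exceeds a sequence length")
  hits <- cpp_seed_extend(toupper(query), toupper(target),
                          as.integer(k), as.integer(min_len),
                          min_identity, as.integer(match),
                          as.integer(mismatch), as.integer(gap),
                          as.integer(x_drop))
  hits[order(-hits$score), , drop = FALSE]
}

#' Flag SEMS whose flanking sequence matches the Y haplotype
#'
#' The cross-mapping diagnostic: a SEMS outside the declared SLR is
#' suspicious when the reference sequence flanking it is similar to the
#' Y (SLR-Y) haplotype, because reads from a Y-hemizygous source absent
#' from a female-derived reference will map onto such paralogous sequence
#' and mimic male-specific heterozygosity.  For each non-SLR record the
#' +/- `flank` window around the site is aligned against `slr_y_sequence`;
#' the record is flagged `crossmap_suspect` when a hit of identity at
#' least `min_identity` covers the site position (within `edge_slop`
#' bases: a cross-mapping SEMS is by construction a mismatch between the
#' paralog and the hemizygous source, and a local alignment trims
#' terminal mismatches, so a site at the very edge of the paralogous
#' tract sits just outside the reported hit).  SLR records pass through
#' unflagged (NA).
#'
#' @param sems data.frame of SEMS records from [classify_sems()] with a
#'   filled `in_slr` column.
#' @param female_reference named character vector of chromosome sequences.
#' @param slr_y_sequence the Y haplotype sequence of the SLR.
#' @param flank flank size in bp (default 500); truncated at contig ends.
#' @param min_identity minimum hit identity (default 0.9).
#' @param edge_slop tolerance in bp for sites at a hit boundary
#'   (default 10).
#' @param k,min_len,match,mismatch,gap,x_drop aligner settings, as in
#'   [seed_extend_align()].
#' @return `sems` with a logical `crossmap_suspect` column appended.
#' @export
flag_crossmap_sems <- function(sems, female_reference, slr_y_sequence,
                               flank = 500L, min_identity = 0.9,
                               edge_slop = 10L,
                               k = 13L, min_len = 50L, match = 1L,
                               mismatch = -2L, gap = -2L, x_drop = 20L) {
  suspect <- rep(NA, nrow(sems))
  todo <- which(!vapply(sems$in_slr, isTRUE, TRUE))
  if (!length(todo)) {
    sems$crossmap_suspect <- suspect
    return(sems)
  }
  windows <- character(length(todo))
  site_in_window <- integer(length(todo))
  for (j in seq_along(todo)) {
    i <- todo[j]
    chrom_seq <- female_reference[[sems$chrom[i]]]
    if (is.null(chrom_seq)) stopf("chromosome %s absent from the reference",
                                  sems$chrom[i])
    lo <- max(0L, sems$pos0[i] - flank)
    hi <- min(nchar(chrom_seq), sems$pos0[i] + flank + 1L)
    windows[j] <- substr(chrom_seq, lo + 1L, hi)
    site_in_window[j] <- sems$pos0[i] - lo  # 0-based within the window
  }
  # the Y haplotype is indexed once and reused for every flank window
  hit_list <- cpp_seed_extend_multi(toupper(windows), toupper(slr_y_sequence),
                                    as.integer(k), as.integer(min_len),
                                    min_identity, as.integer(match),
                                    as.integer(mismatch), as.integer(gap),
                                    as.integer(x_drop))
  for (j in seq_along(todo)) {
    hits <- hit_list[[j]]
    suspect[todo[j]] <- any(hits$qstart - edge_slop <= site_in_window[j] &
                              hits$qend + edge_slop > site_in_window[j] &
                              hits$identity >= min_identity)
  }
  sems$crossmap_suspect <- suspect
  sems
}

# maximum-score chain of hits, non-overlapping on the chimera
# (weighted interval scheduling; small overlaps tolerated and trimmed)
chain_hits <- function(hits, allowed_overlap = 10L) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$qend, hits$qstart)
  hits <- hits[o, , drop = FALSE]
  n <- nrow(hits)
  best <- numeric(n + 1L)  # best[i+1]: best score among first i hits
  takes <- vector("list", n + 1L)
  takes[[1L]] <- integer(0)
  for (i in seq_len(n)) {
    # last j whose qend fits before this hit's qstart (with slack)
    j <- 0L
    for (cand in (i - 1L):0L) {
      if (cand == 0L) { j <- 0L; break }
      if (hits$qend[cand] <= hits$qstart[i] + allowed_overlap) {
        j <- cand; break
      }
    }
    take <- best[j + 1L] + hits$score[i]
    if (take > best[i]) {
      best[i + 1L] <- take
      takes[[i + 1L]] <- c(takes[[j + 1L]], i)
    } else {
      best[i + 1L] <- best[i]
      takes[[i + 1L]] <- takes[[i]]
    }
  }
  sel <- hits[takes[[n + 1L]], , drop = FALSE]
  # trim residual overlaps at the midpoint of the overlap
  if (nrow(sel) > 1L) {
    for (i in 2:nrow(sel)) {
      ov <- sel$qend[i - 1L] - sel$qstart[i]
      if (ov > 0L) {
        cut <- sel$qstart[i] + ceiling(ov / 2)
        sel$qend[i - 1L] <- cut
        sel$qstart[i] <- cut
      }
    }
  }
  rownames(sel) <- NULL
  sel
}

#' Decompose a chimeric duplicate into progenitor segments
#'
#' Chimeric duplicate loci arise by segmental duplication that copies,
#' rearranges and partially repeats pieces of one or more progenitor
#' genes.  All local alignments of the chimera against each progenitor
#' are computed, and a maximum-score chain that is non-overlapping on the
#' chimera (while freely reusing and reordering source intervals) is
#' selected by weighted interval scheduling.
#'
#' @param chimera the chimeric sequence.
#' @param progenitors named list/vector of progenitor sequences.
#' @param min_len,min_identity alignment thresholds (defaults 50 / 0.9).
#' @param ... further arguments passed to [seed_extend_align()].
#' @return list with `segments` (data.frame ordered by chimera
#'   coordinate: chimera_start, chimera_end, source, source_start,
#'   source_end, strand, identity, score) and `coverage_fraction` of the
#'   chimera.
#' @export
decompose_chimeric <- function(chimera, progenitors, min_len = 50L,
                               min_identity = 0.9, ...) {
  if (!length(progenitors)) stopf("need at least one progenitor")
  if (is.null(names(progenitors))) stopf("progenitors must be named")
  all_hits <- list()
  for (nm in names(progenitors)) {
    h <- seed_extend_align(chimera, progenitors[[nm]], min_len = min_len,
                           min_identity = min_identity, ...)
    if (nrow(h)) { h$source <- nm; all_hits[[nm]] <- h }
  }
  empty <- data.frame(chimera_start = integer(0), chimera_end = integer(0),
                      source = character(0), source_start = integer(0),
                      source_end = integer(0), strand = character(0),
                      identity = numeric(0), score = integer(0))
  if (!length(all_hits))
    return(list(segments = empty, coverage_fraction = 0))
  hits <- do.call(rbind, unname(all_hits))
  sel <- chain_hits(hits)
  if (!nrow(sel)) return(list(segments = empty, coverage_fraction = 0))
  segments <- data.frame(chimera_start = sel$qstart,
                         chimera_end = sel$qend,
                         source = sel$source,
                         source_start = sel$tstart,
                         source_end = sel$tend,
                         strand = sel$strand,
                         identity = sel$identity,
                         score = sel$score,
                         stringsAsFactors = FALSE)
  segments <- segments[order(segments$chimera_start), , drop = FALSE]
  rownames(segments) <- NULL
  list(segments = segments,
       coverage_fraction = sum(segments$chimera_end -
                                 segments$chimera_start) / nchar(chimera))
}
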