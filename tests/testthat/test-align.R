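test_that("self-alignment covers the full sequence at identity 1", {
  set.seed(61)
  s <- random_dna(500)
  h <- seed_extend_align(s, s)
  expect_identical(nrow(h), 1L)
  expect_identical(c(h$qstart, h$qend, h$tstart, h$tend), c(0L, 500L, 0L, 500L))
  expect_identical(h$strand, "+")
  expect_equal(h$identity, 1.0)
  expect_identical(h$score, 500L)
})

test_that("a reverse complement aligns full length on the minus strand", {
  set.seed(62)
  s <- random_dna(400)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h <- seed_extend_align(rc, s)
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "-")
  expect_identical(h$qend - h$qstart, 400L)
  expect_equal(h$identity, 1.0)
})

test_that("k below 4 and oversized k are rejected", {
  expect_error(seed_extend_align("ACGTACGTACGT", "ACGTACGTACGT", k = 3L),
               ">= 4")
  expect_error(seed_extend_align("ACGTAC", "ACGTACGTACGT", k = 8L),
               "exceeds")
})

test_that("alignment is deterministic and score-symmetric for best hits", {
  set.seed(63)
  a <- random_dna(300)
  b <- paste0(random_dna(40), mutate_dna(substr(a, 51, 250), 0.05),
              random_dna(40))
  h1 <- seed_extend_align(a, b)
  h2 <- seed_extend_align(a, b)
  expect_identical(h1, h2)
  h3 <- seed_extend_align(b, a)
  expect_identical(max(h1$score), max(h3$score))
})

test_that("reported scores never exceed, and best approaches, the SW optimum", {
  set.seed(64)
  checked_close <- 0L
  for (i in 1:100) {
    n <- sample(60:200, 1)
    a <- random_dna(n)
    if (i %% 2 == 0) {
      # plant shared homology so seeds exist
      core_len <- sample(50:min(150, n), 1)
      core <- substr(a, 1, core_len)
      b <- paste0(random_dna(sample(0:30, 1)),
                  mutate_dna(core, runif(1, 0, 0.05)),
                  random_dna(sample(0:30, 1)))
    } else {
      b <- random_dna(sample(60:200, 1))
    }
    opt <- oracle_sw_score2(a, b)
    h <- seed_extend_align(a, b, min_len = 10L, min_identity = 0)
    if (nrow(h)) expect_lte(max(h$score), opt)
    if (opt >= 50) {
      expect_gte(max(h$score, 0L), 0.9 * opt)
      checked_close <- checked_close + 1L
    }
  }
  expect_gt(checked_close, 20L)  # the bound was actually exercised
})

test_that("ungapped hit identities recompute from the sequences", {
  set.seed(65)
  a <- random_dna(400)
  # isolated substitutions every 25 bp: register shifts cannot pay off,
  # so the optimal path is strictly ungapped and identity is positional
  ch <- strsplit(a, "")[[1]]
  mut_at <- seq(13, 390, by = 25)
  for (i in mut_at) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  b <- paste(ch, collapse = "")
  h <- seed_extend_align(a, b)
  expect_identical(nrow(h), 1L)
  expect_identical(h$length, h$qend - h$qstart)           # no gap columns
  expect_identical(h$qend - h$qstart, h$tend - h$tstart)
  qs <- strsplit(substr(a, h$qstart + 1L, h$qend), "")[[1]]
  ts <- strsplit(substr(b, h$tstart + 1L, h$tend), "")[[1]]
  expect_equal(h$identity, mean(qs == ts), tolerance = 1e-9)
  expect_gte(h$identity, 0.9)
})

test_that("N bases never seed and score as mismatches", {
  set.seed(66)
  a <- random_dna(100)
  expect_identical(nrow(seed_extend_align(strrep("N", 100), a)), 0L)
  withN <- paste0(substr(a, 1, 50), "N", substr(a, 52, 100))
  h <- seed_extend_align(withN, a)
  expect_identical(nrow(h), 1L)
  expect_equal(h$identity, 99 / 100, tolerance = 1e-9)
})

test_that("chaining matches the exhaustive oracle on small instances", {
  set.seed(67)
  for (rep_i in 1:30) {
    n <- sample(3:10, 1)
    qstart <- sample(0:300, n)
    qend <- qstart + sample(20:80, n, replace = TRUE)
    hits <- data.frame(qstart = qstart, qend = qend,
                       tstart = qstart, tend = qend,
                       strand = "+", identity = 1,
                       score = sample(10:100, n, replace = TRUE),
                       source = "A", stringsAsFactors = FALSE)
    got <- slrscan:::chain_hits(hits)
    want <- oracle_best_chain(hits$qstart, hits$qend, hits$score)
    expect_equal(sum(got$score), want)
  }
})

test_that("an exact 3-segment chimera decomposes with exact breakpoints", {
  set.seed(68)
  A <- random_dna(800); B <- random_dna(600)
  segs <- list(A = list(seq = A, interval = c(100L, 350L)),
               A2 = list(seq = A, interval = c(500L, 700L)),
               B = list(seq = B, interval = c(0L, 150L)))
  chim <- make_chimeric_duplicate(segs, c("A", "B", "A2"))
  dec <- decompose_chimeric(chim$chimera, c(A = A, B = B))
  expect_identical(nrow(dec$segments), 3L)
  expect_identical(dec$segments$source, c("A", "B", "A"))
  expect_identical(dec$segments$chimera_start,
                   chim$truth_layout$chimera_start)
  expect_identical(dec$segments$chimera_end, chim$truth_layout$chimera_end)
  expect_identical(dec$segments$source_start,
                   chim$truth_layout$source_start)
  expect_equal(dec$coverage_fraction, 1.0)
})

test_that("a repeated segment is reported twice with the same source", {
  set.seed(69)
  A <- random_dna(500)
  segs <- list(P = list(seq = A, interval = c(0L, 120L)),
               E = list(seq = A, interval = c(300L, 450L)))
  chim <- make_chimeric_duplicate(segs, c("P", "E", "P"))
  dec <- decompose_chimeric(chim$chimera, c(A = A))
  expect_identical(nrow(dec$segments), 3L)
  reps <- dec$segments[dec$segments$source_start == 0L, ]
  expect_identical(nrow(reps), 2L)
  expect_identical(reps$source_end, c(120L, 120L))
})

test_that("no homology yields an empty decomposition", {
  set.seed(70)
  dec <- decompose_chimeric(random_dna(300), c(A = random_dna(300)))
  expect_identical(nrow(dec$segments), 0L)
  expect_equal(dec$coverage_fraction, 0)
  expect_error(decompose_chimeric("ACGT", list()), "at least one")
})

test_that("cross-mapping screen flags paralogous flanks and spares the rest", {
  cfg <- tiny_config(seed = 71L)
  refs <- build_references(cfg)
  sim <- simulate_population(cfg, refs$truth, "female")
  slr <- list(chrom = "chrS", start = 140000, end = 200000)
  sems <- classify_sems(filter_sites(sim$genotypes), sim$sex,
                        slr_interval = slr)
  flagged <- flag_crossmap_sems(sems, refs$female_reference,
                                refs$truth$y_haplotype)
  expect_true(all(is.na(flagged$crossmap_suspect[flagged$in_slr])))
  art <- flagged[!flagged$in_slr, ]
  expect_gt(nrow(art), 0L)
  expect_true(all(art$crossmap_suspect))
  # an unrelated non-SLR SEMS-like record is not flagged
  fake <- sems[1, ]
  fake$chrom <- "chrA"; fake$pos0 <- 90000L; fake$in_slr <- FALSE
  got <- flag_crossmap_sems(fake, refs$female_reference,
                            refs$truth$y_haplotype)
  expect_false(got$crossmap_suspect)
})

test_that("paralog identity below the screen threshold is not flagged", {
  cfg <- tiny_config(seed = 72L, paralog_map = list(
    list(source = c(150000L, 151000L), target_chrom = "chrA",
         target = c(50000L, 51000L), identity = 0.7)))
  refs <- build_references(cfg)
  sems <- data.frame(site = 1L, chrom = "chrA", pos0 = 50500L,
                     ref = "A", alt = "G", pattern = "XY",
                     n_conf_f = 12L, n_conf_m = 10L,
                     n_missing_f = 0L, n_missing_m = 0L,
                     in_slr = FALSE, p_exact = 1e-6,
                     stringsAsFactors = FALSE)
  got <- flag_crossmap_sems(sems, refs$female_reference,
                            refs$truth$y_haplotype, min_identity = 0.9)
  expect_false(got$crossmap_suspect)
})
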