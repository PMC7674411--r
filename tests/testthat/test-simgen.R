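test_that("config validation rejects malformed scenarios", {
  expect_error(tiny_config(n_males = 0L), "each sex")
  expect_error(sim_config(slr_interval = c(701000L, 900000L)),
               "abut the end")
  expect_error(tiny_config(yhs_intervals = list(c(10L, 500L))),
               "within the SLR")
  expect_error(tiny_config(yhs_intervals = list(c(150000L, 151000L),
                                                c(150500L, 152000L))),
               "disjoint")
  expect_error(tiny_config(paralog_map = list(
    list(source = c(150000L, 150500L), target_chrom = "chrA",
         target = c(1000L, 1500L), identity = 0.95),
    list(source = c(150000L, 150500L), target_chrom = "chrA",
         target = c(1200L, 1700L), identity = 0.95))),
    "overlap each other")
  expect_error(tiny_config(paralog_map = list(
    list(source = c(1000L, 2000L), target_chrom = "chrA",
         target = c(1000L, 2000L), identity = 0.95))),
    "inside a YHS")
  expect_error(tiny_config(mismap_fraction = 1.5), "rates")
})

test_that("references differ only as planted: lengths, divergence, paralogs", {
  # no hemizygous insertions: equal lengths, differences only at
  # X/Y-divergent SLR sites
  cfg0 <- tiny_config(yhs_intervals = list(), paralog_map = list())
  refs0 <- build_references(cfg0)
  f <- refs0$female_reference; y <- refs0$y_substituted_reference
  expect_identical(nchar(f), nchar(y))
  expect_identical(f[["chrA"]], y[["chrA"]])
  diff_pos <- which(strsplit(f[["chrS"]], "")[[1]] !=
                      strsplit(y[["chrS"]], "")[[1]]) - 1L
  expect_identical(diff_pos, refs0$truth$true_sems$pos0)
  expect_true(all(diff_pos >= cfg0$slr_interval[1]))

  # a single 34,800-bp insertion lengthens the Y sex chromosome by exactly
  # that amount
  cfg1 <- sim_config(yhs_intervals = list(YHS1 = c(720000L, 754800L)),
                     paralog_map = list())
  refs1 <- build_references(cfg1)
  expect_identical(nchar(refs1$y_substituted_reference[["chr19"]]) -
                     nchar(refs1$female_reference[["chr19"]]), 34800L)

  # identity 1.0 paralog: the target subsequence equals its source exactly
  cfg2 <- tiny_config(paralog_map = list(
    list(source = c(150000L, 150500L), target_chrom = "chrA",
         target = c(50000L, 50500L), identity = 1.0)))
  refs2 <- build_references(cfg2)
  tgt <- substr(refs2$female_reference[["chrA"]], 50001L, 50500L)
  yhs1 <- refs2$truth$true_yhs
  src <- substr(refs2$y_substituted_reference[["chrS"]],
                yhs1$start[1] + 1L, yhs1$start[1] + 500L)
  expect_identical(tgt, src)
  expect_identical(nrow(refs2$truth$artifact_sites), 0L)
})

test_that("generator is deterministic given the seed", {
  cfg <- tiny_config(seed = 7L)
  r1 <- build_references(cfg); r2 <- build_references(cfg)
  expect_identical(r1, r2)
  s1 <- simulate_population(cfg, r1$truth, "female")
  s2 <- simulate_population(cfg, r2$truth, "female")
  expect_identical(s1, s2)
  r3 <- build_references(tiny_config(seed = 8L))
  expect_false(identical(r1$female_reference, r3$female_reference))
})

test_that("truth invariants hold: artifact sites autosomal, sexes complete", {
  refs <- build_references(tiny_config(seed = 3L))
  tr <- refs$truth
  expect_true(all(tr$artifact_sites$chrom == "chrA"))
  expect_true(all(tr$artifact_sites$pos0 >= 50000L &
                    tr$artifact_sites$pos0 < 51000L))
  expect_identical(as.integer(table(tr$sex_of)[c("F", "M")]), c(12L, 10L))
  expect_false(anyDuplicated(names(tr$sex_of)) > 0)
  # Y haplotype length = X + total insertions
  expect_identical(nchar(tr$y_haplotype),
                   nchar(tr$x_haplotype) + sum(tr$true_yhs$length))
})

test_that("window depths are Poisson with mean depth*c/2", {
  cfg <- tiny_config(seed = 11L)
  refs <- build_references(cfg)
  sim <- simulate_population(cfg, refs$truth, "female")
  # diploid windows on the autosome, one sample: mean within 3 SE of 20
  on_a <- sim$coverage$grid$chrom == "chrA"
  x <- sim$coverage$depth[on_a, 1]
  n <- length(x)
  expect_gt(n, 900)
  se <- sqrt(20 / n)
  expect_lt(abs(mean(x) - 20), 3 * se)
  # chi-square goodness of fit against Poisson(20), pooled tails
  br <- c(-Inf, 12:28, Inf)
  obs <- table(cut(x, br))
  p <- diff(ppois(c(-Inf, 12:28, Inf), 20))
  gof <- stats::chisq.test(as.vector(obs), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("hemizygous copy number drives depth under the Y reference", {
  cfg <- tiny_config(seed = 5L)
  refs <- build_references(cfg)
  sim <- simulate_population(cfg, refs$truth, "y_substituted")
  yhs1 <- refs$truth$true_yhs[1, ]
  w <- sim$coverage$grid$chrom == yhs1$chrom &
    sim$coverage$grid$start >= yhs1$start & sim$coverage$grid$end <= yhs1$end
  sex <- refs$truth$sex_of[sim$coverage$sample_ids]
  # females carry no copy: depth exactly zero
  expect_true(all(sim$coverage$depth[w, sex == "F"] == 0L))
  # males carry one copy: mean near depth/2
  m_depth <- sim$coverage$depth[w, sex == "M"]
  expect_lt(abs(mean(m_depth) - 10), 3 * sqrt(10 / length(m_depth)))
})

test_that("mismapping induces the exact male-het/female-hom artifact", {
  cfg <- tiny_config(seed = 9L)
  refs <- build_references(cfg)
  sim <- simulate_population(cfg, refs$truth, "female")
  art <- refs$truth$artifact_sites
  expect_gt(nrow(art), 20)
  key <- paste(sim$genotypes$sites$chrom, sim$genotypes$sites$pos0)
  rows <- match(paste(art$chrom, art$pos0), key)
  rows <- rows[!is.na(rows)]
  sex <- refs$truth$sex_of[sim$genotypes$sample_ids]
  g <- sim$genotypes$geno[rows, , drop = FALSE]
  expect_true(all(g[, sex == "F"] == 0L))
  # closed-form Poisson tail: P(het) = P(Pois(mu*lambda/2) >= 2)
  p_het <- 1 - ppois(1, 0.8 * 20 / 2)
  expect_gt(p_het, 0.99)
  expect_gt(mean(g[, sex == "M"] == 1L), 0.98)

  # mu = 0: no artifact sites are ever called
  cfg0 <- tiny_config(seed = 9L, mismap_fraction = 0)
  refs0 <- build_references(cfg0)
  sim0 <- simulate_population(cfg0, refs0$truth, "female")
  key0 <- paste(sim0$genotypes$sites$chrom, sim0$genotypes$sites$pos0)
  expect_false(any(paste(art$chrom, art$pos0) %in% key0))
})

test_that("true SEMS sites carry the fully sex-linked pattern", {
  cfg <- tiny_config(seed = 13L)
  refs <- build_references(cfg)
  for (mode in c("female", "y_substituted")) {
    sim <- simulate_population(cfg, refs$truth, mode)
    ts <- refs$truth$true_sems
    pos <- if (mode == "female") ts$pos0 else ts$pos0_y
    key <- paste(sim$genotypes$sites$chrom, sim$genotypes$sites$pos0)
    rows <- match(paste(ts$chrom, pos), key)
    expect_false(anyNA(rows))
    sex <- refs$truth$sex_of[sim$genotypes$sample_ids]
    g <- sim$genotypes$geno[rows, , drop = FALSE]
    expect_true(all(g[, sex == "M"] == 1L))
    expect_true(all(g[, sex == "F"] %in% c(0L, 2L)))
  }
})

test_that("reference-mode mismatch with truth is rejected", {
  cfg <- tiny_config(seed = 2L)
  refs <- build_references(cfg)
  cfg2 <- tiny_config(seed = 4L)
  expect_error(simulate_population(cfg2, refs$truth, "female"),
               "not produced")
})

test_that("chimeric duplicates concatenate segments with exact truth layout", {
  set.seed(1)
  segs <- list(P = list(seq = random_dna(400), interval = c(0L, 150L)),
               E1 = list(seq = random_dna(300), interval = c(50L, 200L)),
               H = list(seq = random_dna(500), interval = c(100L, 400L)))
  # single segment, no mutation: chimera equals the source subsequence
  one <- make_chimeric_duplicate(segs["P"], "P")
  expect_identical(one$chimera, substr(segs$P$seq, 1, 150))
  # repeated label: double length, two layout rows
  two <- make_chimeric_duplicate(segs, c("P", "P"))
  expect_identical(nchar(two$chimera), 300L)
  expect_identical(nrow(two$truth_layout), 2L)
  # 8 segments, 7 from one progenitor: layout bookkeeping
  ord <- c("P", "E1", "P", "E1", "H", "P", "E1", "P")
  eight <- make_chimeric_duplicate(segs, ord, mutation_rate = 0.01, seed = 5L)
  expect_identical(nrow(eight$truth_layout), 8L)
  expect_identical(sum(eight$truth_layout$label != "H"), 7L)
  expect_identical(eight$truth_layout$chimera_end,
                   cumsum(eight$truth_layout$chimera_end -
                            eight$truth_layout$chimera_start))
  expect_error(make_chimeric_duplicate(list(), character(0)), "at least one")
})
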