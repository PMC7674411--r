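test_that("window grid tiles each chromosome exactly", {
  g <- window_grid(c(a = 250L, b = 100L), 100L)
  expect_identical(g$start[g$chrom == "a"], c(0L, 100L, 200L))
  expect_identical(g$end[g$chrom == "a"], c(100L, 200L, 250L))  # short tail
  expect_identical(nrow(g[g$chrom == "b", ]), 1L)
  expect_true(all(g$end > g$start))
})

test_that("depth categorisation uses the 0 / 1-2 / >=3 coding", {
  expect_identical(categorize_depth(c(0, 1, 2, 3, 7)), c(0L, 1L, 1L, 2L, 2L))
  expect_error(categorize_depth(c(1, -2)), "negative")
  # monotone: higher depth never lowers the category
  d <- 0:50
  expect_true(all(diff(categorize_depth(d)) >= 0))
})

test_that("strict window flags match a brute-force check", {
  set.seed(31)
  n_f <- 7L; n_m <- 6L
  ids <- c(sprintf("F%d", 1:n_f), sprintf("M%d", 1:n_m))
  sex_table <- data.frame(sample = ids,
                          sex = c(rep("F", n_f), rep("M", n_m)))
  grid <- window_grid(c(z = 50000L), 100L)
  depth <- matrix(rpois(nrow(grid) * (n_f + n_m), 4), nrow(grid))
  # plant a male-specific stripe and a female-specific stripe
  depth[101:120, 1:n_f] <- 0L
  depth[101:120, n_f + 1:n_m] <- 30L
  depth[301:305, 1:n_f] <- 30L
  depth[301:305, n_f + 1:n_m] <- 0L
  cov <- coverage_matrix(grid, depth, ids)
  cats <- categorize_depth(cov)
  got <- window_sex_match(cats, sex_table, mode = "strict")
  want <- vapply(seq_len(nrow(grid)), function(i) {
    cf <- cats$categories[i, 1:n_f]; cm <- cats$categories[i, n_f + 1:n_m]
    if (all(cm == 2L) && all(cf == 0L)) "male_specific"
    else if (all(cf == 2L) && all(cm == 0L)) "female_specific"
    else "none"
  }, "")
  expect_identical(got$flag, want)
  expect_identical(which(got$flag == "male_specific"), 101:120)
  expect_identical(which(got$flag == "female_specific"), 301:305)
})

test_that("uniform windows are never flagged", {
  ids <- c("F1", "F2", "M1", "M2")
  sex_table <- data.frame(sample = ids, sex = c("F", "F", "M", "M"))
  grid <- window_grid(c(z = 300L), 100L)
  all2 <- coverage_matrix(grid, matrix(5L, 3, 4), ids)
  got <- window_sex_match(categorize_depth(all2), sex_table, "strict")
  expect_true(all(got$flag == "none"))
  rel <- window_sex_match(categorize_depth(all2), sex_table, "relaxed")
  expect_true(all(rel$flag == "none"))
  expect_true(all(rel$p == 1))
})

test_that("relaxed mode controls false flags on random categories", {
  set.seed(53)
  n <- 20L
  ids <- sprintf("s%02d", 1:n)
  sex_table <- data.frame(sample = ids,
                          sex = rep(c("F", "M"), each = n / 2))
  grid <- window_grid(c(z = 1000000L), 100L)
  depth <- matrix(sample(0:5, nrow(grid) * n, replace = TRUE), nrow(grid))
  cov <- coverage_matrix(grid, depth, ids)
  got <- window_sex_match(categorize_depth(cov), sex_table, "relaxed",
                          alpha = 0.01)
  # Bonferroni at alpha = 0.01 over 10^4 windows: expect ~zero flags
  expect_lte(sum(got$flag != "none"), 1L)
})

test_that("regions merge runs, honour gaps and minimum lengths", {
  grid <- window_grid(c(z = 2000L), 100L)
  fl <- rep("none", 20)
  fl[c(3, 4, 6, 10, 15)] <- "male_specific"
  r0 <- merge_regions(fl, grid, max_gap_windows = 0L)
  expect_identical(nrow(r0), 4L)
  expect_identical(r0$start, c(200L, 500L, 900L, 1400L))
  r1 <- merge_regions(fl, grid, max_gap_windows = 1L)
  expect_identical(nrow(r1), 3L)
  expect_identical(r1$start[1], 200L)
  expect_identical(r1$end[1], 600L)
  expect_identical(r1$n_windows[1], 3L)
  r2 <- merge_regions(fl, grid, max_gap_windows = 1L, min_windows = 2L)
  expect_identical(nrow(r2), 1L)
  expect_identical(merge_regions(rep("none", 20), grid),
                   merge_regions(character(20) |> replace(TRUE, "none"), grid))
  expect_identical(nrow(merge_regions(rep("none", 20), grid)), 0L)
  # disjoint and sorted
  r3 <- merge_regions(replace(fl, 12, "female_specific"), grid,
                      max_gap_windows = 2L)
  expect_true(!is.unsorted(r3$start))
  expect_true(all(r3$start[-1] >= r3$end[-nrow(r3)] |
                    r3$specificity[-1] != r3$specificity[-nrow(r3)]))
})

test_that("an isolated 100-bp window becomes a 100-bp region", {
  grid <- window_grid(c(z = 3000L), 100L)
  fl <- replace(rep("none", 30), 17, "male_specific")
  r <- merge_regions(fl, grid)
  expect_identical(nrow(r), 1L)
  expect_identical(r$end - r$start, 100L)
})

test_that("planted hemizygous intervals are recovered with exact bounds", {
  cfg <- tiny_config(seed = 19L)
  refs <- build_references(cfg)
  sim <- simulate_population(cfg, refs$truth, "y_substituted")
  regions <- call_sex_regions(sim$coverage, sim$sex, mode = "strict")
  truth <- refs$truth$true_yhs
  big <- truth[truth$length >= 300L, ]
  for (i in seq_len(nrow(big))) {
    hit <- regions[regions$chrom == big$chrom[i] &
                     regions$start < big$end[i] &
                     regions$end > big$start[i] &
                     regions$specificity == "male_specific", ]
    expect_identical(nrow(hit), 1L)
    expect_lte(abs(hit$start - big$start[i]), 100L)
    expect_lte(abs(hit$end - big$end[i]), 100L)
  }
  # no false regions outside the planted intervals
  outside <- regions[!vapply(seq_len(nrow(regions)), function(i)
    any(regions$chrom[i] == truth$chrom &
          regions$start[i] < truth$end & regions$end[i] > truth$start),
    TRUE), ]
  expect_identical(nrow(outside), 0L)
})

test_that("nothing is flagged under the female reference (YHS not representable)", {
  cfg <- tiny_config(seed = 23L)
  refs <- build_references(cfg)
  sim <- simulate_population(cfg, refs$truth, "female")
  regions <- call_sex_regions(sim$coverage, sim$sex, mode = "strict")
  expect_identical(nrow(regions), 0L)
  cmp <- compare_references(regions,
                            call_sex_regions(
                              simulate_population(cfg, refs$truth,
                                                  "y_substituted")$coverage,
                              sim$sex, mode = "strict"),
                            truth_yhs = refs$truth$true_yhs)
  det <- cmp$truth_detectability
  expect_false(any(det$representable_in_female_reference))
  expect_true(all(det$detected_in_y_reference[
    refs$truth$true_yhs$length >= 300L]))
})

test_that("identical region lists are reference-independent", {
  r <- data.frame(chrom = "z", start = 0L, end = 500L,
                  specificity = "male_specific", n_windows = 5L,
                  neg_log10_p = NA_real_)
  cmp <- compare_references(r, r)
  expect_true(all(cmp$regions$status == "reference_independent"))
  expect_error(compare_references(r, r, samples_female = c("a", "b"),
                                  samples_y = c("a", "c")),
               "different sample sets")
})

test_that("region presence check mirrors a PCR panel and flags exceptions", {
  cfg <- tiny_config(seed = 29L)
  refs <- build_references(cfg)
  sim <- simulate_population(cfg, refs$truth, "y_substituted")
  yhs1 <- refs$truth$true_yhs[1, ]
  region <- data.frame(chrom = yhs1$chrom, start = yhs1$start,
                       end = yhs1$end, specificity = "male_specific")
  conf <- check_region_presence(region, sim$coverage, sim$sex)
  expect_true(all(conf$concordant))
  # plant an exception: one male deleted for the region
  depth2 <- sim$coverage$depth
  w <- sim$coverage$grid$chrom == yhs1$chrom &
    sim$coverage$grid$start >= yhs1$start &
    sim$coverage$grid$end <= yhs1$end
  victim <- which(sim$sex$sex == "M")[1]
  depth2[w, victim] <- 0L
  cov2 <- coverage_matrix(sim$coverage$grid, depth2,
                          sim$coverage$sample_ids)
  conf2 <- check_region_presence(region, cov2, sim$sex)
  bad <- conf2[!conf2$concordant, ]
  expect_identical(nrow(bad), 1L)
  expect_identical(bad$sample, sim$sex$sample[victim])
  # a region off the grid errors
  off <- data.frame(chrom = "nope", start = 0L, end = 100L,
                    specificity = "male_specific")
  expect_error(check_region_presence(off, sim$coverage, sim$sex),
               "outside the coverage grid")
})
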