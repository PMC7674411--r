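# Desk-scale scenario used by unit tests: a 300-kb genome with a 60-kb
# peritelomeric SLR, three hemizygous insertions and one autosomal paralog.
tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_females = 12L, n_males = 10L,
    chrom_lengths = c(chrS = 200000L, chrA = 100000L),
    slr_interval = c(140000L, 200000L),
    yhs_intervals = list(YHS1 = c(150000L, 154800L),
                         YHS2 = c(170000L, 170600L),
                         YHS3 = c(180000L, 180100L)),
    paralog_map = list(list(source = c(150000L, 151000L),
                            target_chrom = "chrA",
                            target = c(50000L, 51000L),
                            identity = 0.95)),
    snp_density = 0.001, xy_divergence = 0.002,
    seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

tiny_sex_table <- function(truth) {
  data.frame(sample = names(truth$sex_of), sex = unname(truth$sex_of),
             stringsAsFactors = FALSE)
}

# random genotype matrix over 1-2 chromosomes with some planted patterns
random_genotype_matrix <- function(n_sites, n_f, n_m, miss = 0.05,
                                   plant_sems = 0L) {
  n <- n_f + n_m
  sex <- c(rep("F", n_f), rep("M", n_m))
  geno <- matrix(sample(c(0L, 1L, 2L), n_sites * n, replace = TRUE),
                 n_sites, n)
  if (miss > 0) geno[runif(length(geno)) < miss] <- NA_integer_
  if (plant_sems > 0L) {
    rows <- sample(n_sites, plant_sems)
    geno[rows, sex == "F"] <- sample(c(0L, 2L), plant_sems * n_f,
                                     replace = TRUE)
    geno[rows, sex == "M"] <- 1L
  }
  sites <- data.frame(chrom = "chr1", pos0 = seq_len(n_sites) * 10L,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  ids <- c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m)))
  list(gm = genotype_matrix(sites, geno, ids),
       sex_table = data.frame(sample = ids, sex = sex,
                              stringsAsFactors = FALSE),
       sex = sex)
}
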