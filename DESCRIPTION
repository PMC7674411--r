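Package: slrscan
Title: Discovery of Sex-Linked Regions from Population Genotypes and Read Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating sex-linked regions (SLRs) and Y-specific
    hemizygous sequences (YHSs) in dioecious species from population
    resequencing summaries. Implements exact sex-matched SNP screening
    (SEMS), a per-site exact association scan, categorical read-coverage
    scanning for presence/absence association with sex, dual-reference
    (female vs Y-substituted) comparison that eliminates cross-mapping
    false positives, trio-based X/Y haplotype phasing of the SLR, a
    k-mer seed-and-extend local aligner for cross-mapping diagnosis and
    chimeric-duplicate decomposition, and a synthetic dioecious-genome
    generator with full ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
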