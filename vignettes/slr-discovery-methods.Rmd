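---
title: "Discovering sex-linked regions from population genotypes and read coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-linked regions from population genotypes and read coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrscan)
```

## The problem

In dioecious species with young sex chromosomes, the sex-determining locus
sits in a small non-recombining sex-linked region (SLR).  Two population
signals localise it from short-read resequencing of sexed individuals:

1. **SEMS** ("SNPs exactly matching with sexes").  Under male heterogamety
   (XY), a site fully linked to the Y is heterozygous in every male and
   homozygous in every female.  The mirror pattern indicates ZW (female
   heterogamety).

2. **Coverage presence/absence.**  Sequence present only on the Y
   haplotype (a Y-specific hemizygous sequence, YHS) has no X counterpart:
   mapped against a reference that contains it, every male shows reads
   and every female shows none.  SNP screens are blind to such sequence,
   which is why the coverage scan is run alongside.

Both signals are distorted by the reference.  When the reference genome is
derived from a female, reads from Y-only sequence have nowhere to map and
pile up on autosomal paralogs, where the fixed differences between the
Y-source and the paralog masquerade as perfectly sex-linked heterozygosity
— false SEMS far from the SLR.  Re-running the scan against a reference in
which the SLR is replaced by the Y haplotype (the "Y-substituted"
reference) removes the cross-mapping source, so artifact SEMS vanish while
genuine SLR SEMS persist.  slrscan implements this dual-reference logic
end to end, together with a sequence-similarity diagnostic that flags each
suspect SEMS independently of the coverage evidence.

## The statistical model

**Association scan.**  Each site is reduced to a 2x2 table of
heterozygote-carrier status against sex over non-missing calls, and scored
with the two-sided Fisher exact p-value — the sum of hypergeometric
probabilities not exceeding that of the observed table.  A kinship-aware
mixed model adds nothing here: the decisive criterion is the *exact*
genotype-sex match, the synthetic populations are unrelated, and perfect
separation is maximal under both statistics, so the ranking is preserved.
Under perfect separation with $n_F$ females and $n_M$ males the p-value
reaches its floor $1/\binom{n_F+n_M}{n_M}$ (about $10^{-27.5}$ at 49/46).
Multiple testing uses the Bonferroni cutoff $\alpha/n$ only; no FDR is
applied.

**SEMS with imperfect data.**  "Homozygous in all females" constrains each
individual, not the population: a mix of hom-ref and hom-alt females
still matches (a strict single-class mode is available).  Missing data are
handled by requiring a per-sex call rate of at least 0.9 at the site
(mirroring the 10% missingness site filter) and conformity of every
non-missing call; `strict_missing` demands complete data.

**Coverage categories.**  Window depths collapse to three levels: 0 (no
read), 1 (depth 1-2), 2 (depth >= 3, the conventional threshold for a
reliably mapped window).  The strict window test demands category 2 in
every carrier-sex sample and category 0 in every other-sex sample; the
relaxed test collapses to present/absent, applies the Fisher exact test
with the Bonferroni cutoff, and tolerates a declared fraction of dropouts
(`min_present_fraction`, `max_absent_leak`).  Category 1 counts as
"present" for the relaxed test but never satisfies the strict one.

**Boundary refinement.**  At hemizygous depth $\lambda/2 = 10$ the strict
per-window test loses windows to Poisson sampling: a male window drops
below 3 reads with probability $P(\mathrm{Pois}(10) \le 2) \approx
0.0028$, so with 46 males roughly 12% of true YHS windows fail the strict
test somewhere.  Merged strict runs therefore tolerate small interior
gaps (`max_gap_windows = 2`) and are extended outwards while every
carrier-sex sample keeps at least one read and the other sex has none —
a criterion that essentially never crosses into diploid sequence, where
the absence sex has Poisson(20) reads.  A single-window (100 bp) insertion
has no run to rescue it; its recovery rests on the relaxed test, for which
one dropout among 46 carriers is immaterial.

**Trio phasing.**  Because a son's X is the X he inherited from his
sequenced mother, her genotypes phase his heterozygous SLR sites: mother
homozygous gives X = her allele, Y = the other; double heterozygotes are
irreducibly ambiguous without read-backed evidence and are reported as
such, never imputed — the SLR does not recombine, but unphased genotype
codes carry no within-individual phase to propagate.  Opposite homozygotes
in mother and son are Mendelian conflicts, reported with a summary rate
(a high rate signals a sample mix-up).  Homozygous sites in the son phase
trivially, and the same conflict rule applies to them.

**Aligner.**  The cross-mapping diagnostic and the chimeric-duplicate
decomposition use a self-contained seed-and-extend local aligner: exact
k-mer seeds (k = 13) on both strands, greedy clustering of seed matches
into diagonal bands, banded local dynamic programming over each cluster
(+1 match, -2 mismatch, -2 per gap base), x-drop splitting of paths whose
running score dips more than `x_drop = 20` below its maximum, and
recursive re-alignment of the split pieces so each reported hit is a
locally optimal alignment with clean boundaries.  N never seeds and
scores as a mismatch.  Chimera decomposition chains hits by weighted
interval scheduling, non-overlapping on the chimera but free to reuse and
reorder source intervals, since chimeric duplicates repeat and rearrange
progenitor pieces.

## The synthetic scenario

The generator draws the observable *outcomes* of mapping and variant
calling rather than reads: the downstream inference consumes only
genotype calls and windowed depths, so read-level simulation would add
cost without exercising more of the method.  Its defaults anchor the
package's tests at the operating point of a poplar-scale study:

| parameter | default | meaning |
|---|---|---|
| `n_females` / `n_males` | 49 / 46 | sexed, unrelated samples |
| `mean_depth` | 20 | reads per diploid 100-bp window; hemizygous windows draw Poisson(10) |
| `slr_interval` | 299 kb | peritelomeric SLR on a 1-Mb sex chromosome (plus a 500-kb autosome) |
| `yhs_intervals` | 34.8 kb / 4.3 kb / 100 bp | hemizygous insertions, window-aligned |
| `paralog_map` | one 2-kb copy at 95% identity | autosomal attractor for cross-mapped reads |
| `xy_divergence` | 0.0015 /bp | X/Y substitution rate in the SLR; ~450 fully sex-linked sites, the density at which SEMS screens operate in practice |
| `snp_density` | 0.001 /bp | background HWE SNPs outside the SLR |
| `mismap_fraction` | 0.8 | fraction of hemizygous-source reads that cross-map when the reference lacks the source |
| `min_alt_reads` | 2 | cross-mapped reads needed for the caller model to emit a het |
| `missing_rate`, `genotype_error_rate` | 0 | corruption is opt-in |
| `window_size` | 100 bp | coverage grid |

The genome is desk-scale (1.5 Mb) so that a full dual-reference analysis
runs in about a second; all structural proportions (SLR fraction, YHS
sizes, paralog identity) match the full-scale setting.  Cross-mapped
depth on a paralog window is Poisson($\mu \lambda / 2$) in the
heterogametic sex, and an artifact site is called heterozygous when at
least `min_alt_reads` cross-mapped reads arrive — a closed-form Poisson
tail, $1 - P(\mathrm{Pois}(8) \le 1) \approx 0.997$ per male at the
defaults.  An optional negative-binomial switch (`overdispersion`) is
exposed for depth; the default is Poisson, the simplest model consistent
with the statistics the pipeline consumes.

Design choices a user should know:

* **The SLR abuts the sex-chromosome end** (it is peritelomeric, with
  coordinate zero at the telomere).  This makes every position outside
  the SLR numerically identical under the two references, so SEMS lists
  intersect by plain position; hemizygous insertions shift coordinates
  only inside the SLR, and the generator records both coordinate systems.
* **SLR polymorphism.**  Within the SLR the population segregates only
  the fixed X/Y differences; background X-linked polymorphism is not
  simulated.  Population samples are unrelated; the only pedigree is one
  mother-son pair.
* **Trio model.**  The transmitted maternal X *is* the reference X
  haplotype (as it is when the assembled X of a sequenced son anchors the
  analysis).  Mother heterozygosity `h` places the Y-like allele on her
  untransmitted X at a Bernoulli(h) subset of divergent sites — shared
  ancestral polymorphism — so the expected ambiguous fraction equals `h`
  and every phased site is checkable against truth.
* **Sites inside hemizygous insertions carry no SNP calls**; hemizygous
  presence is a coverage signal, not a genotype signal.
* **Cross-map flag tolerance.**  An artifact SEMS is by construction a
  mismatch between paralog and source, and local alignments trim terminal
  mismatches, so a site at the very edge of the paralogous tract can sit
  a few bases outside the reported hit; the screen therefore accepts hits
  within `edge_slop = 10` bp of the site.

What passing tests on this generator do **not** show about real data:
mapping-quality pathologies, repeat-driven coverage heterogeneity,
batch- or sample-level depth trends (a per-sample `depth_scale` is
exposed but defaults to uniform), linked selection, relatedness among
samples, and reference errors are all outside the model.  The pipeline's
thresholds are honest defaults, not guarantees, on data with those
features.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; VCF positions are 1-based
  on output, BED output is 0-based.
* Degenerate 2x2 tables (a zero margin) score p = 1.
* Fisher two-sided sums use a `1 + 1e-7` relative slack when comparing
  hypergeometric point masses, the standard guard against floating-point
  ties.
* `filter_sites` with everything removed warns and returns an empty
  matrix rather than erroring; empty flag vectors merge to empty region
  lists.
* Genotype codes are integers 0/1/2 with `NA` for missing; unparsable GT
  strings in a VCF become `NA` with a warning, unknown samples are an
  error.
* Ambiguous phased sites emit IUPAC two-base codes; conflicts and missing
  sites emit N.
* The aligner caps any single DP subregion at $8 \times 10^7$ cells; at
  the intended query scales (flank windows and gene-sized chimeras) this
  guard is never reached.

## Problem sizes used by the test suite

Unit tests run on a 300-kb two-chromosome genome (12 F / 10 M) where a
full scan takes well under a second; the acceptance suite re-runs the
complete pipeline at the default operating point above across 20 seeds,
plus a 5-seed ZW mirror in which every sex-specific behaviour must flip.
The exact-test oracle enumerates every 2x2 table with margins up to 12
against an independent implementation, and the SEMS classifier is checked
against brute-force enumeration including all $4^6$ genotype assignments
for 3 females and 3 males at one site.

## Known limitations

* The relaxed coverage test treats windows independently; it does not
  model spatial correlation of mapping artifacts.
* Breakpoints of decomposed chimera segments are accurate to a few bases,
  not exact, when point mutations sit at segment boundaries.
* Phasing consumes genotype codes, not reads; ambiguity that read-backed
  phasing could resolve is reported as ambiguous.
* The dual-reference comparison assumes the two call sets share sample
  ids and that non-SLR coordinates agree between references, which holds
  when the references differ only inside the SLR.
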