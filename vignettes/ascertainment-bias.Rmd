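---
title: "Simulating GWAS ascertainment bias and correcting genetic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GWAS ascertainment bias and correcting genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascertainr)
```

## The problem

A disease association can only be discovered where the statistical power
to detect it is appreciable, and power for a case-control allelic test is
maximized at intermediate risk-allele frequencies in the *study*
population. Most published GWAS used European cohorts and genotyping
arrays whose content was itself ascertained in small, largely European
discovery panels. Because non-African populations passed through the
out-of-Africa bottleneck, their allele frequencies have drifted further
from the ancestral state than African frequencies. The discovered set of
disease loci is therefore frequency-biased in a direction that depends on
whether the risk allele is ancestral or derived, even under the null
hypothesis that true disease risks are identical in every population.
This package simulates that discovery process end to end and implements
the ancestral/derived-aware correction of unweighted genetic risk scores.

## The synthetic panel: what it emulates

Real analyses of this question use phase 3 1000 Genomes frequencies. To
make every stage testable without downloads, `synthetic_panel()`
generates a panel with the statistical structure the analysis relies on:

1. **Standing variation.** Pre-divergence derived-allele frequencies are
   drawn from the neutral SFS, `P(p0 = i/n_chrom) ∝ 1/i` on a 1000-point
   grid, so rare derived (common ancestral) alleles dominate.
2. **Hierarchical drift.** Population frequencies follow a hierarchical
   Balding–Nichols model: `AFR ~ BN(p0, f_afr)`; a shared out-of-Africa
   intermediate `~ BN(p0, f_ooa)`; each of AMR/EAS/EUR/SAS then drifts
   independently `~ BN(·, f_pop)`. `BN(p, f)` is a Beta distribution
   with mean `p` and variance `f·p(1−p)`, so the model is
   mean-preserving and non-African populations both carry more drift
   variance than Africa and are correlated with one another through the
   bottleneck — the two features that drive the cohort asymmetry.
   Defaults are `f_afr = 0.01`, `f_ooa = 0.10`, `f_pop = 0.02`: the
   simplest mean-preserving setting that reproduces the qualitative
   bottleneck asymmetry. They are calibration knobs, not estimates of
   human demography; loci that drift to fixation are kept, as real
   panels contain population-fixed sites.
3. **Array ascertainment.** A SNP enters the synthetic array if it is
   polymorphic in a discovery sample of `d` chromosomes from the
   discovery population (default EUR, `d = 4`):
   `P(retain) = 1 − q^d − (1−q)^d`. Small `d` maximizes the
   intermediate-frequency enrichment that commercial arrays exhibit.
4. **Genotypes and disease tables.** Individual genotypes are
   Hardy–Weinberg binomial draws from the population frequency; disease
   tables sample distinct loci with a configurable ancestral-risk
   proportion (default 0.44, matching the known catalog) and a 7-way
   category label. Category weights default to uniform — the real
   catalog's category sizes are an empirical detail the analyses here do
   not depend on.

What the generator does *not* emulate: linkage disequilibrium (every
locus is independent), selection, admixture, and the site-specific
quirks of real array content. Tests that pass on this panel therefore
demonstrate that the *machinery* behaves as the drift-plus-power model
predicts, not that the synthetic magnitudes match the published
empirical values, which require the real panel and curated catalog.

## The power engine

`analytic_power()` computes the power of the two-sided 1-df allelic
test. Penetrances `(f0, f1, f2)` come from the genotype relative risk γ
under the chosen inheritance model (additive `f1 = γ f0`,
`f2 = (2γ−1) f0`; dominant `f1 = f2 = γ f0`; recessive `f1 = f0`,
`f2 = γ f0`), with `f0` solved from the prevalence identity
`K = (1−p)² f0 + 2p(1−p) f1 + p² f2`. Expected case/control allele
frequencies follow, and power is the normal-approximation tail
probability of the allele-frequency contrast with null variance at the
pooled frequency and alternative variance from the two binomials. At
γ = 1 the formula returns exactly α; at `p ∈ {0, 1}` it returns exactly
0 (a monomorphic site can never be accepted, which the rejection sampler
requires). The published analysis used the GAS/CaTS calculator without
restating its formula, and whether it used the allelic or the trend test
is unstated; the allelic form is implemented, isolated behind
`analytic_power()`, and validated against `monte_carlo_power()` — an
independent simulation of binomial allele counts tested by chi-square —
across a 36-point model × frequency × effect grid.

Two numerical choices matter inside the simulator. First, the vectorized
power path clamps penetrances into [0, 1]: gamma-distributed effect
sizes occasionally imply `f2 > 1` at low frequencies, which the scalar
API treats as an error (inconsistent parameters) but which must not
abort a 10⁶-draw replicate; clamping caps such draws at the boundary.
Second, power at monomorphic sites is defined as 0 rather than
undefined.

## The rejection sampler

`rejection_sample_associations()` implements discovery exactly as the
design specifies: draw a uniform test SNP from the platform pool, look
up its risk-allele frequency in the study cohort (ancestral risk uses
`1 − DAF`; `MIX` cohorts use the unweighted five-population mean), draw
locus-specific γ (per-population under the noise/shift models; power
uses the study population's γ, `MIX` the mean), accept if
`U(0,1) < power`, and stop at `n_target` distinct loci. Duplicated
acceptances are rejected — "a set of n loci" is a set — and a draw cap
(default 10⁸) guards pools with vanishing acceptance probability.
Replicate `i` of `run_replicates()` uses a deterministic child seed so
any replicate is reproducible in isolation. Whether the reference
analysis re-drew γ per draw or fixed it per SNP is unstated; γ is
re-drawn per draw here. The shifted effect models retain the
per-population noise in addition to the +0.5 shift, since the noise is
introduced before the shifted distributions in the source description.

## Empirical statistics and their conventions

- `frequency_difference_by_state()` reports the mean per-locus
  `AFR − pooled non-AFR` risk-frequency difference by risk-allele state;
  pooling is the unweighted mean of the four non-African populations
  (a chromosome-count-weighted pool is available via
  `pooled_nonafrican_daf(weights =)`). Ties count as "not higher in
  Africa" and are reported.
- `daf_bin_differences()` bins loci by across-population mean DAF with a
  closed lowest bin `[0, 0.2]` and right-closed bins above, so "DAF ≤
  0.2" lands in the young-allele bin.
- `allele_age()` defaults to the drift estimator `2N·p/(1−p)`
  generations, the unique standard frequency-based form that gives
  125,000 years at `p = 0.2`, `N = 10⁴`, 25 y/generation; the
  Kimura–Ohta segregating-age form is available via `method =
  "kimura"`.
- `paired_wilcoxon_frequency_test()` is exact for ≤ 25 non-zero
  differences and uses the normal approximation above.

## Risk scores and the correction

Raw scores are unweighted sums of risk-allele counts per category (no
odds-ratio weighting: categories pool heterogeneous phenotypes whose
effect sizes are not comparable). Standardization is a Z-score across
*all* individuals pooled; corrected scores replace each count with an
effective count — `count − δ_anc` at ancestral-risk loci,
`count + δ_der` at derived-risk loci — and are mapped through the
*uncorrected* mean and SD, so corrected and uncorrected scores live on
the same scale. The default constants `δ_anc = 0.1902 = 2 × 9.51%` and
`δ_der = 0.1082 = 2 × 5.41%` are the published empirical values (the
source prints 5.40% in one place and 5.41% in another; the constant is
built from 5.41%). `estimate_correction_constants()` recomputes both
from any panel/table pair as twice the mean state-specific frequency
difference. One structural point the synthetic panel makes visible: the
correction shifts a category's African scores by
`−L_anc δ_anc + L_der δ_der`, so for categories whose ancestral
proportion makes those terms cancel the correction is near-neutral; its
benefit concentrates in categories with skewed ancestral proportions.
By default only individuals labeled AFR are corrected, matching the
intended use; `correct_populations` generalizes this.

## Problem sizes and reproducibility

The simulation experiments in the test suite run at reduced but
statistically meaningful scale, chosen so the full suite completes in
about a minute: 20,000-SNP panels, 300 accepted loci per replicate
(versus 3036 in the reference design), 100 replicate pairs for the
cohort-ordering checks, and 50 replicates per cell on a 4-point
log₁₀ sample-size grid. Comparisons between noisy replicate means carry
two standard errors of Monte-Carlo slack computed from the replicates
themselves. All generators and simulations take explicit seeds;
pipeline outputs embed md5 checksums in a manifest and are byte-stable
under reruns.

## Known limitations

Independent loci only (no LD pruning or clumping); no selection or
admixture in the generator; the allelic (not trend or logistic) test;
no effect-size-weighted or LD-aware risk scores; the published
empirical magnitudes (+9.51%, −5.40%, +1.15% overall) are reproducible
only with the real 1000 Genomes panel and curated locus table, which
are external inputs to `run_empirical_analysis()`.
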