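---
title: "Methods: thermal-time-driven architecture simulation and genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-time-driven architecture simulation and genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllosim)
```

`phyllosim` couples two models that are usually studied apart: a
quantitative-genetics layer that predicts per-genotype growth parameters
from SNP markers (RR-BLUP), and a first-year tree architecture simulator in
which those parameters drive primary growth and branching. The target
system is an apple F1 bi-parental population (116 genotypes, two clonal
replicates) phenotyped at the end of its first growing season. This
vignette documents the models, their assumptions, the defaults, and the
numerical choices, in the package's own terms.

## Thermal time

Daily degree-days are accumulated between a base of 7 °C and an upper
threshold of 35 °C, by either of two estimators:

* **daily-mean**: `max(0, min(Tmean, 35) − 7)`;
* **single-sine**: the day's temperature course is modelled as one
  symmetric sine cycle between Tmin and Tmax and the area between the
  thresholds is integrated in closed form.

The upper threshold uses a *horizontal cutoff*: time spent above 35 °C
contributes at the 35 °C rate. This is the common single-sine convention;
the literature also knows vertical and intermediate cutoffs, and the choice
only matters on days whose maximum exceeds the threshold (rare in the
emulated climate). We apply the 35 °C cap in the daily-mean method as well,
for symmetry; with Mediterranean daily means this is almost always
inactive. Correctness of the closed form is pinned against numerical
quadrature of the same sine curve (agreement below 0.01 GDD over 1000
random days).

The growing season is fixed at April 15 (budburst, season day 1) to
September 30, both inclusive. Cumulative GDD over that window is the
simulator's only clock; the calendar enters nowhere else, and the series is
tested to be shift-invariant.

## Growth and branching model

A trunk is an ordered sequence of metamers (node + internode + leaf). The
first 8 metamers are preformed in the bud and present at budburst; their
organ dimensions default to the genotype's values times a configurable
scale factor (default 1), since only neoformed dimensions are measured.
Neoformed metamers appear deterministically: the neoformed count at day
*d* is `floor(RLE_GDD × cumulative_GDD(d))`, so the *phyllochron* (thermal
time between successive leaves) is `1/RLE_GDD` — 30 GDD at the population
mean rate of 0.033 leaves·GDD⁻¹, i.e. about one leaf every 3 days early in
the season and every 2 days in summer. Organ expansion dynamics are
omitted: final internode length and leaf area are applied immediately,
which leaves the end-of-season architecture unchanged.

Sylleptic (same-season) laterals arise stochastically. When the apex emits
the metamer of rank *k*, the node at rank *k − r_k* (if it exists and has
not been tested before) undergoes exactly one Bernoulli trial with

> P_d = clip( a_syll × mean(RLE over the n_days days up to d), 0, 1 )

where `RLE_d = RLE_GDD × GDD_d` is the daily leaf-emergence rate. The rank
offset `r_k` represents apical inhibition: the last `r_k` nodes below the
apex never branch. Defaults `r_k = 20`, `n_days = 7` are the combination
retained by the virtual-experiment grid search (below). Two conventions
required a decision:

* the averaging window holds exactly `n_days` terms (days
  `d − n_days + 1 … d`); a printed form with `n_days + 1` terms over a
  divisor of `n_days` would not be a mean, and the package resolves the
  mismatch in favour of a true mean, consistently in the simulator and in
  the estimator;
* days before budburst contribute zero RLE to the window, and preformed
  nodes are eligible under the same rule as neoformed ones — the
  near-zero early-season RLE makes their branching probability tiny, which
  reproduces the observed near-absence of laterals at the trunk base.

The linear probability is clipped to [0, 1]; at realistic rates it stays
far from the bound. Because the emission schedule is deterministic given
parameters and climate, the expected number of laterals is an exact sum of
per-event probabilities (`expected_nb_syll()`), which the Monte-Carlo mean
over seeded replicates must match — this dual route is tested within three
Monte-Carlo standard errors at 1000 trees.

Population runs derive per-tree seeds from a master seed with a counter, so
results are reproducible and independent of evaluation order. The reported
per-genotype lateral count is the mean over 5 replicate simulations by
default (the trait is stochastic; all other traits are deterministic).

## Parameter estimation

* **RLE_GDD** is the OLS slope of cumulative leaf counts on cumulative
  single-sine GDD at the observation days, per genotype. Regressing the
  cumulative series avoids differencing noise; on noiseless linear data the
  slope is exact, and weekly sampling of the floor schedule biases it by
  less than 0.002 leaves·GDD⁻¹.
* **Model choice for RLE**: four candidate linear models spanning the two
  contrasts of interest (temperature in/out; genotype-specific response
  in/out) are compared by BIC (−2logL + k·logN): constant rate, constant
  rate + genotype, rate ∝ daily-mean GDD, rate ∝ single-sine GDD with
  per-genotype slopes. Generative self-consistency is tested: data built
  with genotype-specific single-sine slopes select the last model; constant
  data select the first.
* **a_syll** is estimated in closed form by inverting the expected lateral
  count: each day from `d_b` (the day rank `r_k` appears) to season end,
  the expected number of eligibility events is `RLE_GDD × GDD_d`, each
  firing with probability `a_syll × RLE_GDD × windowmean(GDD)`, so
  `a_syll = N_syll / (RLE_GDD² × Σ_d windowmean(GDD, d) × GDD_d)`.
  The squared-rate term is verified by an exact algebraic identity test
  rather than assumed; the estimator round-trips simulated populations
  within 10% at 500 trees.
* **(r_k, n_days)** come from a grid search over {5, 10, 15, 20} ×
  {3, 7, 10}: simulate the population at each cell, compute the rank-wise
  RMSE between simulated and observed pooled frequency profiles of
  laterals along the trunk, take the argmin (ties toward smaller `r_k`,
  then smaller `n_days`). Branching is rare, so the profile is pooled over
  genotypes. We use 10 replicate trees per genotype per cell for
  Monte-Carlo precision; self-generated profiles are recovered at (20, 7).

## Variance components and heritability

The study design is balanced (2 replicates; optionally 2 years), so
variance components use closed-form balanced ANOVA estimators, which for
the one-way random model coincide with REML whenever the genotypic
component is nonnegative (tested against lme4). Unbalanced input is
rejected rather than approximated. Negative components are truncated at
zero.

Broad-sense heritability of genotype means is
`h² = σ_G² / (σ_G² + σ_e²/n)` (single year) and
`h² = σ_G² / (σ_G² + σ_I²/a + σ_e²/(n·a))` (two years, year fixed,
genotype and interaction random; the year effect is F-tested against the
interaction). The 95% interval is the exact F-quantile construction for
balanced designs: `h²` equals one minus the reciprocal of the relevant
mean-square ratio, so quantiles of that F-ratio translate directly into
interval bounds; simulated coverage is ≈95% over 1000 datasets.

Phenotypic correlations use replicate-level values; genotypic correlations
use h²-shrunken centered genotype means. Because the shrinkage is a
per-trait scalar, the Pearson correlation is identical to that of raw
genotype means — both variants are exposed and tested equal. Significance
is by Pearson's test.

## Genomic prediction

Markers are coded −1 (A/B heterozygote) / +1 (A/A homozygote); only loci
heterozygous in exactly one parent are informative in the F1 design, and
the filter lives in data loading, not in the solver. The model is

> Y = μ + X g + e, g ~ N(0, I σ_g²), e ~ N(0, I σ_e²)

fitted on replicate-level rows (each genotype's marker row duplicated per
replicate; 232 × 2160 at study scale). The variance ratio
λ = σ_e²/σ_g² is estimated by REML: the phenotypes are projected onto an
orthonormal basis of error contrasts (normalized Helmert columns,
orthogonal to the intercept), the projected genetic covariance `A'XX'A` is
eigendecomposed once, and the profiled restricted likelihood is maximized
over log λ by Brent search (bracket 10⁻⁶…10⁶, tolerance 10⁻⁸). The
intercept is the GLS solution and effects are the BLUP
`g = X'(XX' + λI)⁻¹(y − μ)`. The solver is verified against an
independent dense-matrix restricted likelihood (400-point λ-grid plus
local refinement) to below 10⁻³ relative error on the ratio, intercept and
effects. A zero marker matrix degenerates cleanly to the intercept model.

BLUP predictions are shrunken, so for phenotypic-scale parameter values the
effects are rescaled by `sd(Y)/sd(G)` where `G = μ + W ĝ` on the genotype
matrix `W`; after rescaling the predicted dispersion equals `sd(Y)` exactly
(an identity, tested to machine precision). Sample standard deviations
(n−1) are used throughout.

Cross-validation assigns *genotypes* to folds, so replicates always travel
together. With 116 genotypes and 10 folds the sizes are six of 12 and four
of 11. Fold accuracy is the correlation between predicted values and
observed genotype means of the held-out fold, k-fold accuracy the mean
(±SD) over folds; leave-one-out accuracy is the single correlation over
all genotypes. Fold assignments are seeded and stored. On synthetic data
the expected ordering — within-sample ≥ leave-one-out ≥ k-fold — and the
accuracy–heritability monotonicity are tested on averages over replicate
datasets; a pure-noise trait cross-validates at zero within Monte-Carlo
error.

## Validation metrics and pipeline

Simulated and observed integrative traits (leaf count, trunk length,
lateral count) are compared by Pearson r, `RMSE = sqrt(mean((O − S)²))`,
`nRMSE = RMSE / mean(O)` (stored as a fraction, printed as %), and
`BIAS = mean(S − O)` (positive = overestimation). The bias–variance
identity `RMSE² = BIAS² + var(S − O)` is exact and tested. Lateral counts
are compared as means over 5 simulation replicates.

`run_pipeline()` chains generation (or CSV loading), RR-BLUP fitting of
the four parameters, rescaling and prediction, simulation under two
climates with true (genotype-mean) and predicted parameters, and the
validation table (2 climates × 3 traits). Reports are deterministic given
the configuration — serialized reports from repeated runs are
byte-identical — and each stage failure carries a stage tag.

## Synthetic data: what it emulates, and what not

The generator's defaults are the study conditions: 116 genotypes × 2
replicates; 2160 markers spread over 17 chromosomes (the apple karyotype),
each heterozygous in one randomly assigned parent, inherited under the
Haldane (no-interference) map function on an 80 cM chromosome; polygenic
normal effects, with genetic values rescaled so the realized genetic
variance matches each trait's target heritability at the design's
replicate count (means/SDs/h²: 0.033 ± 0.003 / 0.59 for the emergence
rate, 2.02 ± 0.28 cm / 0.86 for internode length, 25.54 ± 5.99 cm² / 0.40
for leaf area, −1.25 ± 1.03 / 0.72 for the log branching coefficient —the
log is used because the coefficient itself is right-skewed). An optional
single-QTL mode plants one locus carrying a chosen share of a trait's
genetic variance (e.g. 16.9%) on an otherwise polygenic background.

Climate is a seasonal Gaussian bump peaking in late July plus AR(1) daily
noise (ρ = 0.6 — the within-season autocorrelation is not constrained by
data and was chosen once as a realistic value), with an additive offset
calibrated by root finding so the season's single-sine GDD hits the target
within 1% (2278 GDD for the reference season; the second preset targets
98% of that without the early-season warm pulse, reproducing a
warmer-start/cooler-summer contrast between two experiment years).

Features of real data deliberately *not* emulated: marker-density
variation along chromosomes, crossover interference, segregation
distortion, parental haplotype phase variation, non-Gaussian residuals,
spatial field trends, and any environmental driver of growth other than
temperature. Passing tests therefore demonstrate internal consistency of
the methods under the stated generative assumptions, not transferability
to field data — the latter is exactly the gap the validation metrics are
designed to expose when real observations are supplied.

## Numerical choices and degenerate inputs

* Emission uses `floor()`, so a vanishing rate yields exactly the 8
  preformed metamers; a zero rate disables eligibility and branching.
* Probabilities are clipped to [0, 1]; negative coefficients and rates are
  rejected at construction.
* The REML bracket 10⁻⁶…10⁶ in λ covers traits from almost-perfectly
  heritable to pure noise; boundary solutions indicate a degenerate trait
  and surface as such (σ_g² → 0 with the intercept model as explicit
  fallback for a zero marker matrix).
* Grid-search ties break toward the smallest `r_k`, then smallest
  `n_days`.
* Variance components are truncated at zero *after* the mean-square
  arithmetic, so confidence intervals use the untruncated F-ratio.
* All stochastic code takes explicit seeds; population and pipeline seeds
  are derived from a master seed with fixed offsets (all below 2³¹).

## Problem sizes used in the test suite

The suite favours the smallest sizes at which each property is decisive:
quadrature checks use 1000 random days; Monte-Carlo branching checks 500–
1000 trees on the 169-day season; REML oracle comparisons a 30-genotype ×
51-marker instance; heritability coverage 1000 balanced datasets of 40 × 2;
cross-validation properties 30–116 genotypes with 51–170 markers; the
grid-search recovery 50 genotypes × 10 replicates per cell over 5 master
seeds; and the end-to-end pipeline 25 genotypes × 68 markers. Full
study-scale runs (116 × 2160) are exercised once in the generator checks.

## Known limitations

* The branching model is linear in the recent emergence rate; saturating
  or threshold responses are out of scope, though the observed
  concentration of laterals mid-trunk suggests the real link may be
  sharper than linear.
* Temperature is the only environmental driver; water and carbon status
  are absent, so between-year transfer is expected to degrade — the
  package measures that degradation rather than modelling it.
* The two-year heritability supports exactly two years (`a = 2`), matching
  the design; other layouts are rejected explicitly.
* The genomic model is strict ridge (common marker variance); Bayesian
  variable-selection alternatives are not implemented.
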