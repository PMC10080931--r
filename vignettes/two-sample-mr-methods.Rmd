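---
title: "Two-sample Mendelian randomization with mrpipe: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
library(dplyr)
```

## The design

Mendelian randomization (MR) uses genetic variants as instrumental variables
for a modifiable exposure. Because alleles are assigned at meiosis, a variant
robustly associated with the exposure is, under the instrumental-variable
assumptions, independent of the confounders that plague observational
epidemiology; its association with a disease outcome then carries causal
information about the exposure. In the *two-sample* flavour, the SNP-exposure
and SNP-outcome associations come from different, non-overlapping GWAS, which
is what makes analyses of large public summary statistics possible.

`mrpipe` implements this workflow end to end for summary-level data:
reproductive-behaviour exposures such as age at first sex (AFS) or age at
first birth (AFB) against binary cardiovascular outcomes are the motivating
use case, but nothing in the package is specific to them.

The chain of assumptions the estimators need, and the diagnostics attached to
each, are:

1. **Relevance** — instruments must predict the exposure. Quantified per SNP
   by the variance explained and the F-statistic (`instrument_qc()`); the
   conventional floor is F ≥ 10.
2. **No confounding of the instrument** — addressed by design (meiosis), and
   by multivariable MR for measured heritable confounders (`mvmr_ivw()`).
3. **Exclusion restriction** — no effect on the outcome except through the
   exposure. Violations (horizontal pleiotropy) are probed by the MR-Egger
   intercept and by comparing the inverse-variance weighted (IVW) estimate
   with the weighted median.

## Instrument selection and harmonization

Instruments are selected at genome-wide significance, `p < 5e-8`, with a
*strict* inequality; a p-value exactly at the threshold is excluded. The same
strictness applies to every threshold in the package (outcome-association
exclusion at `5e-8`, proxy LD at `r2 > 0.60`, palindromic minor allele
frequency above `0.42`), so boundary values always fall on the retained side
of a ">" rule and the excluded side of a "<" rule exactly as the rules read.

Harmonization (`harmonize()`) expresses both studies' effects on a common
effect allele:

* identical allele pairs are kept; reversed pairs have the outcome beta
  negated and the effect-allele frequency (EAF) reflected;
* pairs that only match after complementing the outcome alleles (A↔T, C↔G)
  are treated the same way after the strand correction — for non-palindromic
  SNPs this is unambiguous;
* palindromic SNPs (A/T, C/G) carry no strand information in their allele
  letters. We resolve them by EAF concordance: the orientation whose outcome
  EAF falls on the same side of 0.5 as the exposure EAF is taken. Because the
  call becomes unreliable as the frequency approaches 0.5, palindromic SNPs
  with exposure-side minor allele frequency above 0.42 are excluded outright
  (`palindromic-ambiguous`), as are palindromes with a missing EAF on either
  side. A MAF of exactly 0.42 is retained. The exposure side defines the MAF
  test because the instrument GWAS is typically the larger and
  better-characterized source.
* instruments reaching `p < 5e-8` in the outcome GWAS are excluded as
  outcome loci rather than exposure instruments;
* instruments absent from the outcome GWAS can be replaced from a
  user-supplied LD proxy table at `r2 > 0.60`. Among eligible proxies the
  highest r² wins, with ties broken lexicographically by rsID so reruns are
  deterministic. Proxy alleles are remapped to the query SNP's alleles
  through the table's allele correspondence; a proxy whose correspondence
  contradicts the outcome record is skipped with a warning.

Every excluded SNP stays in the returned table with exactly one reason, and
`attr(pairs, "log")` keeps the per-stage attrition counts, so an analysis can
always account for its instrument attrition.

## Estimators

With harmonized pairs `(beta_x, beta_y, se_y)` the per-SNP Wald ratio is
`beta_y / beta_x` with first-order standard error `se_y / |beta_x|` (a
second-order form adding the exposure-uncertainty term is available behind
`second_order = TRUE`; it perturbs the weights slightly and is off by
default).

**IVW, multiplicative random effects** (`mr_ivw()`, the primary estimator) is
weighted least squares of `beta_y` on `beta_x` through the origin with
weights `1/se_y^2`. Heterogeneity is Cochran's Q on `L - 1` degrees of
freedom with `I² = max(0, (Q - df)/Q) × 100`, banded as low (≤ 25%), moderate
(25-50%) and high (≥ 50%). The random-effects standard error inflates the
fixed-effect one by `sqrt(Q/df)`, floored at 1, so under-dispersion never
produces an interval narrower than the fixed-effect interval. With a single
SNP the IVW reduces exactly to the Wald ratio.

**Weighted median** (`mr_weighted_median()`) interpolates the
inverse-variance-weighted ratios at cumulative weight 0.5 and is consistent
while valid instruments carry at least half the weight. Its standard error is
a parametric bootstrap (default 1000 replicates) that redraws both betas from
their sampling distributions; the seed is a required argument, so the SE is
bit-reproducible.

**MR-Egger** (`mr_egger()`) adds an intercept to the weighted regression
after orienting all exposure betas non-negative (flipping both members of a
pair is a no-op for every estimator, so this costs nothing and makes the
intercept interpretable as average directional pleiotropy). Inference uses
the t distribution on `L - 2` degrees of freedom, the convention of the
method's source literature, with the same multiplicative overdispersion
floor.

**Multivariable MR** (`mvmr_ivw()`) regresses the outcome betas on all
exposure-beta columns jointly, no intercept, weights `1/se_y^2`; each
coefficient is a direct effect conditional on the other exposures. The
instrument set is the union of each exposure's genome-wide-significant SNPs
(union rather than intersection preserves power; SNPs missing anywhere are
dropped and logged), harmonized to a common allele reference. A
single-exposure call reproduces univariable IVW exactly, which is one of the
package's cross-checks.

**Mediation** (`mr_mediate()`) is two-step MR: the total effect and the
exposure-to-mediator effect come from univariable IVW on the exposure's
instruments; the mediator-to-outcome effect adjusted for the exposure comes
from multivariable MR on the *mediator's* instruments. The indirect effect is
the product of coefficients, its standard error the first-order product rule
with zero covariance (the estimates come from non-overlapping samples — this
is why the synthetic mediator gets its own third sample). The mediated
proportion divides the indirect by the *total* effect — the convention when a
mediated share of a total association is reported — with a ratio delta-method
CI, again with zero numerator-denominator covariance; dividing by
`direct + indirect` instead is available behind the `denominator` flag.
Proportions are never clamped: sign-discordant or >100% decompositions are
reported as-is with a flag, because clamping would hide exactly the cases
that need scrutiny. When the total effect is numerically zero the proportion
is reported as undefined.

## Power and instrument strength

Per-SNP variance explained uses
`R² = 2·EAF(1-EAF)β² / (2·EAF(1-EAF)β² + 2·EAF(1-EAF)N·se²)`, which reduces
algebraically to `z²/(z² + N)` — an identity the tests assert numerically —
and `F = R²(N-2)/(1-R²) ≈ z²` for large N. Aggregate instrument strength sums
per-SNP R² (instruments are LD-pruned lead SNPs, treated as independent).

Binary-outcome power (`mr_power_binary()`) uses the normal approximation with
non-centrality `|ln OR| · sqrt(N · R² · K(1-K))`, where K is the outcome
GWAS's case fraction: power = `Φ(z - z_c) + Φ(-z - z_c)` at two-sided level
α. This is the stated-inputs approximation to the widely used online MR power
calculators — it needs only the sample size, case fraction and variance
explained. A null odds ratio returns exactly α, and power is symmetric in
`OR ↔ 1/OR`. `cvd_outcome_counts()` bundles the published case/control
structure of the five large cardiovascular outcome GWAS so the headline power
computation is reproducible offline; continuous-outcome power is out of scope
(every outcome in the motivating design is binary).

## The synthetic generator

`simulate_two_sample()` exists so that every stage — reading, selection,
harmonization, estimation, mediation — is testable with known ground truth
and no downloads. Its defaults *are* the study conditions the package
targets, chosen once:

* L = 100 instrument SNPs; true SNP-exposure effects `γ ~ N(0.03, 0.01)` in
  SD units of the exposure, which at the default exposure GWAS size
  N = 397,338 (a large biobank behavioural GWAS) gives per-SNP z around 10 —
  comfortably genome-wide significant, like real lead SNPs;
* binary outcome GWAS of N = 977,323 with case fraction 47,309/977,323 (the
  scale of a modern heart-failure meta-analysis), effects on the log-odds
  scale with `se = 1/sqrt(2f(1-f) · N · K(1-K))`;
* causal effect θ = -0.3 (the magnitude of the strongest protective
  association the motivating studies report);
* minor allele frequencies uniform on (0.05, 0.5); 15% of SNPs get
  palindromic allele pairs; 20% of outcome records are reported on the
  opposite allele and 20% on the opposite strand, so harmonization always has
  real work to do. The truth record keeps the uncorrupted orientation;
* pleiotropy off by default; scenario tests switch it on (30% invalid
  instruments with balanced `N(0, 0.01)` or directional `N(0.05, 0.01)`
  direct effects).

The mediation chain (`simulate_mediation_chain()`) adds a mediator measured
in an independent third sample (N = 400,000) with 100 instruments of its own;
defaults `α = 0.3`, `β_m = -0.25`, direct = -0.225 give a total of -0.3 with
25% mediated, the magnitude of the education-mediation signals that motivate
two-step MR here.

What the generator deliberately does **not** model: LD between instruments
(real instruments are pruned lead SNPs), sample overlap between the two GWAS,
winner's curse in instrument discovery, allele-frequency differences between
studies, and population stratification. Passing tests therefore demonstrate
correctness of the estimators and the harmonization logic under the stated
asymptotic model — not robustness to those additional real-data pathologies.

A `sampling_noise = FALSE` switch returns the noise-free expectations
instead of draws; the mediation decomposition `direct + indirect = total`
then holds to machine precision, which the tests exploit.

## Numerical choices and degenerate inputs

* All weighted regressions are solved by explicit normal equations; the MVMR
  design matrix is checked by condition number (fatal above 1e12, reported).
* Overdispersion is always multiplicative and floored at 1; p-values are
  normal for IVW and the weighted median, t on `L - 2` for Egger.
* Egger is refused when all exposure betas coincide (slope unidentifiable);
  ratio estimators drop zero exposure betas with a warning; IVW with one pair
  falls back to the Wald ratio, with none it is fatal.
* The I² banding treats exactly 50% as high and exactly 25% as low.
* Bonferroni classification compares at full precision (0.05/4 = 0.0125 even
  where reports conventionally print 0.013).
* Report tables are rendered with fixed formats and sorted deterministically,
  so identical inputs and seed give byte-identical files.

## Problem sizes in the test suite

The suite validates calibration by simulation at sizes chosen to keep the
whole run inside a couple of minutes while leaving Monte-Carlo error well
below the asserted bands: 1000 replicates for type-I error (band 3-8%), 500
for CI coverage (band 92-98%), 200 each for the pleiotropy-robustness and
mediation-coverage contracts, and 100 random instances for the
estimator-versus-oracle exactness checks at tolerance 1e-8.

## Known limitations

* Proxy records are consumed from a user table; the package does not compute
  LD from a reference panel or query online services.
* The power formula is an approximation to the cited online calculator, not
  a reimplementation of it, and covers binary outcomes only.
* No MR-PRESSO-style outlier removal, mode-based estimators, conditional
  F-statistics, or nonlinear/stratified MR.
* The weighted-median bootstrap treats per-SNP weights as re-estimated per
  draw, which is the conventional but not unique choice.
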