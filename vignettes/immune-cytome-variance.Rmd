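---
title: "Decomposing variability in the peripheral blood immune cytome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing variability in the peripheral blood immune cytome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Flow-cytometric immunophenotyping of healthy adults shows wide person-to-person
differences in the frequencies of peripheral blood immune cell subsets (each
expressed as a percent of its parent gate). Two very different mechanisms can
produce that picture: every individual may hold a stable, characteristic
set-point that differs between people, or individuals may all wander over the
same range so that a single blood draw lands anywhere. Telling these apart
requires serial sampling, and the distinction matters — set-point-like subsets
are candidates for heritable or early-life programming, while fluctuation-driven
subsets point at ongoing environmental exposure.

`cytomevar` implements the full analysis for a longitudinal design (individuals
bled repeatedly over a year, a technical control stained with every batch, and
an independent sibling cohort), together with a synthetic cohort generator that
reproduces the assumed statistical structure so every stage can be verified by
parameter recovery without access to any particular study's raw data.

## The variance model

All stages work on long-format tables of `frequency_pct` per
(`individual_id`, `visit_index`, `subset_id`).

**Mean-normalization.** Subset frequencies span orders of magnitude (well under
0.1% for iNKT-like subsets to above 80% for classical monocytes), so raw
variances are incomparable. Each observation is divided by its subset's grand
mean; normalized values have mean 1 per subset and their variances compare
across subsets (`mean_normalize()`).

**Descriptive decomposition** (`descriptive_variances()`): per subset,

* between-individual variance — sample variance (always the n−1 denominator)
  across individuals of the per-individual mean;
* within-individual variance — unweighted mean of the per-individual sample
  variances across visits (individuals contribute equally; a single-visit
  individual joins the between term via its one value but not the within term);
* technical variance — sample variance of the normalized control values across
  staining runs.

The between term can alternatively be the pooled variance of all observations
(`between = "pooled"`); the per-individual-means definition is the default
because it matches the between/within dichotomy of a paired-bar reading of the
decomposition.

**Model-based decomposition** (`fit_variance_components()`): the one-way
random-intercept model \(y_{ij} = \mu + b_i + e_{ij}\),
\(b_i \sim N(0,\sigma^2_b)\), \(e_{ij} \sim N(0,\sigma^2_w)\), fitted by REML
(lme4). Estimates are bounded at zero and the headline quantity is
\(\mathrm{prop}_w = \sigma^2_w / (\sigma^2_b + \sigma^2_w)\), flagged undefined
when both components vanish. On balanced interior fits REML coincides with the
one-way ANOVA method-of-moments closed form (\(\hat\sigma^2_w = MSW\),
\(\hat\sigma^2_b = (MSB - MSW)/n\)); `anova_variance_components()` implements
that closed form as the independent cross-check. The equivalence is a theorem
only away from the boundary: when \(MSB < MSW\) the truncated moment estimator
keeps \(\hat\sigma^2_w = MSW\) while the REML boundary fit pools toward the
grand variance, so the test suite asserts 10^-6 agreement on interior fits and
agreement of the zero component on boundary draws.

**Outlier exclusion** (`detect_outlier_subsets()`): subsets whose technical
(or between-) variance exceeds the Tukey far-out fence Q3 + 3·IQR (type-7
quantiles) are flagged, excluded from all downstream stages, but retained in
reports. The far-out multiplier is deliberately conservative: the intent is to
catch a subset whose staining is qualitatively unreliable (an iNKT-like
outlier "by a wide margin"), not to trim the tail of an ordinary spread.

**Within-on-between regression** (`regress_within_on_between()`): OLS of
within-individual on between-individual variance across subsets, optionally
with technical variance as a covariate; reports slope, adjusted R², and the
t statistic of the between coefficient.

## Resampling tests

**Permutation test of between vs within** (`permutation_test_variance()`).
Statistic: \(T = \mathrm{var}_{between} - \mathrm{var}_{within}\) on
mean-normalized values. A difference rather than a ratio keeps \(T\) defined
when individuals are internally constant. The null permutes which observations
belong to which individual — destroying individual identity while preserving
every visit count and the marginal distribution, the minimal exchangeability
null for "does individual identity matter". One-sided add-one p-value
\(p = (1 + \#\{T^\ast \ge T\}) / (B + 1)\), so \(p \ge 1/(B+1)\). When a small
input admits at most \(B\) distinct assignments, the null is enumerated
exhaustively and \(p\) is the exact fraction. Defaults: B = 9999 for a single
subset, 999 in batch mode with Benjamini–Hochberg q-values across subsets.

**Sibling concordance** (`sibling_concordance_test()`). Sibling and reference
cohorts are z-scored per subset against their own mean and SD (removing
cohort-level location/scale differences; whether the original analyses pooled
the cohorts before scaling is unknowable from the outside, and separate scaling
is the conservative choice). The statistic is the mean absolute z-difference
over all within-family pairs; the null resamples the same number of *disjoint*
unrelated pairs, without replacement within a draw, from one visit (default
visit 1) of the longitudinal cohort; concordance is evidence of *smaller*
distance, so \(p = (1 + \#\{\bar d^\ast \le \bar d\}) / (B + 1)\). Disjoint
pairs require the reference cohort to hold at least twice as many individuals
as there are sibling pairs. A 37-family cohort against a 43-individual
reference cannot satisfy that, so the pipeline sets `subsample_pairs = TRUE`:
the sibling pairs are seeded-subsampled to `floor(n_ref / 2)` (21 with the
default design), trading power for an exactly matched null; calibration and
power studies in the test suite instead use an 80-individual synthetic
reference so all 37 pairs are kept.

## Fluctuation and mean-variance coupling

Observations are z-scored per subset over the whole longitudinal cohort
(`zscore_transform()`). Each individual's **baseline** is the mean of their
z-scores and their **fluctuation** the sample variance of those z-scores
(`individual_baseline_fluctuation()`). Per subset, Spearman correlation of
baseline against fluctuation across individuals
(`mean_variance_correlation()`) is the environmental-responsiveness signature:
in exposure-driven subsets, upward excursions drag the average up, so
individuals sitting high also fluctuate more. The figure-legend definition
(variance of z-scores) is the default; a dispersion-index variant
(per-individual raw variance over raw mean) is available behind
`variant = "variance_over_mean"` because the two readings circulate for this
quantity.

Spearman p-values follow one rule everywhere (`spearman_test()`): rho is the
Pearson correlation of average ranks; two-sided p by exact enumeration over
all rank permutations for n < 10 and by the t approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) otherwise. Exact enumeration above n = 9
would cost more than the approximation error is worth at the cohort sizes this
package targets.

`rank_concordance()` then asks whether subsets with high between-individual
variance are also the strongly coupled ones — Spearman correlation between the
rank of `var_between` and the rank of the coupling rho across subsets.

## Multivariate structure

PCA of individuals on baselines, fluctuations, or both (`pca_individuals()`):
columns centered, unit-scaled by default (the two feature blocks live on
different scales), singular value decomposition, explained-variance ratios
from squared singular values, and each component's sign fixed so its
largest-magnitude loading is positive (a deterministic tie-break so reruns and
platforms agree). Inter-subset Spearman correlation matrices
(`correlation_matrix()`) take BH-FDR over the strict upper triangle only
(m = k(k−1)/2) and mirror q to the full matrix. `correlation_network()`
filters edges by q and |rho|; pairs sharing a parent gate (or in a direct
parent–child relation) can be dropped as compositional artifacts — frequencies
within one gate sum toward 100%, manufacturing negative correlations — but the
default keeps them so the full network is reproducible. Sex differences use
two-sided Wilcoxon rank-sum tests on per-individual means over visits (exact
null when the combined sample is ≤ 20 without ties) with Bonferroni
adjustment, `min(1, p·m)`.

## The synthetic cohort generator

For individual \(i\) and subset \(s\) the generator draws a stable log-scale
baseline \(b_{is} \sim N(0, \sigma_b^2)\) and observes

\[ y_{ijs} = \mathrm{clamp}\big(\mu_s\,(e^{b_{is}} + \delta_{ijs}),\ 0,\ 100\big),
   \qquad \delta_{ijs} \sim N\big(0,\ (\sigma_w e^{\kappa_s b_{is}})^2\big). \]

Baselines are lognormal — positive, right-skewed, spanning orders of magnitude
across subsets — while visit noise is mean-scaled and, at \(\kappa = 0\),
*level-independent*. That last property is the deliberate design choice in
this model: coupling between an individual's level and their fluctuation
enters only through the visit-noise SD via \(\kappa\), so \(\kappa = 0\)
subsets are an exact independence null for the mean-variance analysis and
\(\kappa > 0\) subsets reproduce the responsive signature. A fully
multiplicative alternative (noise inside the exponential) was rejected because
it couples level and spread on the measurement scale for *every* subset —
under it even \(\kappa = 0\) subsets show strongly positive mean-variance
correlation (around 0.6 at \(\sigma_b = 0.5\)), which would make the stable/
responsive contrast the analysis is built to detect undetectable by
construction. Useful closed forms under the chosen model: \(E[y] = \mu
e^{\sigma_b^2/2}\); within-individual variance \((\mu\sigma_w)^2\) at
\(\kappa=0\); variance of true individual means
\(\mu^2 e^{\sigma_b^2}(e^{\sigma_b^2}-1)\). These are the oracles the
moment-recovery tests freeze.

Clamping into [0, 100] is logged and rare under the default panel (a handful
of values per draw, confined to the most dispersed low-frequency subsets).

Technical replicates: one latent control value per subset (a control donor
drawn from the population), re-stained per run under multiplicative lognormal
noise with unit mean and CV = `technical_cv`. Siblings: per family a shared
component \(g_{fs} \sim N(0, \phi\sigma_b^2)\) plus an individual part
\(u \sim N(0, (1-\phi)\sigma_b^2)\), so \(\phi\) (`sibling_shared_fraction`)
is exactly the within-family intraclass correlation of log baselines.

Default design (the study scale all acceptance checks run at): 43 individuals
× 4 quarterly visits × 35 subsets, 40 replicate runs at 5% technical CV, 37
two-sibling families with \(\phi = 0.5\). The 35-subset panel assigns
plausible population means (0.08%–80% of parent), between-individual log-SDs
of 0.08–0.7, \(\sigma_w = 0.6\,\sigma_b\) throughout (a shared per-subset
scale, which is what makes within- track between-individual variance across
subsets linearly), and \(\kappa = 1\) for the eight exposure-driven subsets
(plasmablasts, EMRA/TEMRA T cells, gamma-delta T, inflammatory monocytes, B1)
versus \(\kappa = 0\) elsewhere. No published effect sizes exist for the
responsive class, so \(\kappa = 1\) is a calibration choice: large enough that
coupling is detectable at 43 individuals with 4 visits in ≥90% of runs, small
enough that the subsets remain realistic. Each output table draws from its own
RNG stream (master seed + fixed offset), so generating replicates never
perturbs the cohort.

What the generator does **not** emulate: cross-subset correlation structure
(baselines are independent across subsets, so a correct correlation-network
null finds ~0 edges on synthetic data), seasonality, age trends, sex effects,
gating-hierarchy compositional constraints, and specific exposures. Passing
tests therefore validate the estimators and their calibration, not any claim
about which real subsets behave which way.

## Numerical choices and degenerate inputs

* Sample variances use n−1 everywhere.
* Negative variance components truncate at 0 with a degenerate flag;
  `prop_within` is NA when both components are 0.
* Zero subset mean (normalization) and zero subset SD (z-scoring) are errors
  naming the subset; constant features are flagged undefined in correlation
  matrices rather than silently dropped.
* Add-one p-values keep permutation/resampling p in (0, 1]; exhaustive
  enumeration replaces sampling when the assignment space is smaller than B.
* Tie handling: average ranks in all Spearman computations; tie-corrected
  normal approximation in rank-sum tests when exactness is unavailable.
* CSV serialization writes numerics with 17 significant digits so write/read
  round trips are bit-exact.
* REML fits tighten the optimizer tolerances (`xtol_abs = 1e-12`) so balanced
  fits agree with the ANOVA closed form to 10^-6.

## Problem sizes

The test suite and acceptance checks run at deliberately chosen scales: the
REML/ANOVA equivalence on 50+ balanced 10×4 datasets; prop_within recovery on
200 replicates of the 43×4 design per variance ratio (0.25, 1, 4); permutation
calibration on 1000 null cohorts at B = 199; coupling detection on 200 cohorts;
sibling calibration on 500 null cohorts (37 families against an 80-individual
reference) plus 200 power runs at \(\phi = 0.8\); FDR null calibration on 500
draws of a 43×33 feature matrix. These sizes put Monte-Carlo error comfortably
inside the asserted bands while keeping a full run in the low minutes on one
core.

## Limitations

* The package analyses relative frequencies only; absolute counts carry
  assay-day confounding this design cannot separate.
* The permutation scheme for the between/within contrast is a reconstruction
  of an underspecified published procedure ("randomly sampled groups of
  individuals"); it is the minimal exchangeability null consistent with that
  description, not a verbatim reimplementation.
* Whether inter-subset correlations should be computed on per-individual mean
  z-scores (default), one visit, or raw pooled observations is a genuine
  degree of freedom; the choice is configurable.
* Sibling concordance is a screen, not a heritability estimate: shared
  households and early-life exposures are not separable from genetics in this
  design.
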