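# cytomevar

Variance structure of the peripheral blood immune cytome from longitudinal
immunophenotyping.

Healthy adults differ widely in the frequencies of their immune cell subsets
(% of parent gate by flow cytometry). `cytomevar` is for immunologists and
biostatisticians who have — or want to design — a serial-sampling study and
need to answer: how much of the population spread reflects stable personal
set-points versus short-term fluctuation versus technical noise? Which subsets
behave as environmentally responsive (an individual's level couples to their
fluctuation)? And do stable subsets run in families?

The package implements, per subset *s* with observations
*y<sub>ij</sub>* (individual *i*, visit *j*):

* **Variance decomposition** on mean-normalized values
  (*y* / subset mean): descriptive between-individual
  (variance of per-individual means), within-individual (mean of
  per-individual variances), and technical (control-sample across staining
  runs) components; the one-way random-intercept model
  *y<sub>ij</sub> = μ + b<sub>i</sub> + e<sub>ij</sub>* by REML with
  prop<sub>w</sub> = σ²<sub>w</sub>/(σ²<sub>b</sub>+σ²<sub>w</sub>);
  Tukey far-out (Q3 + 3·IQR) exclusion of technically unreliable subsets; and
  OLS of within- on between-individual variance across subsets.
* **Permutation test** of T = var<sub>between</sub> − var<sub>within</sub>
  against the individual-label-permutation null, add-one p-values, exhaustive
  enumeration on small inputs.
* **Mean–variance coupling**: per-individual baseline (mean z-score) and
  fluctuation (variance of z-scores), Spearman coupling per subset (exact p
  below n = 10, t-approximation otherwise), and the rank concordance of
  coupling strength with between-individual variance.
* **Multivariate structure**: PCA of individuals on baselines and
  fluctuations, inter-subset Spearman matrices with Benjamini–Hochberg FDR
  over the upper triangle, significant-edge network export (optionally
  dropping compositional same-gate pairs), and Wilcoxon sex comparisons with
  Bonferroni correction.
* **Sibling concordance**: mean |Δz| over within-family pairs against
  resampled disjoint unrelated pairs from one visit of the longitudinal
  cohort.
* **A synthetic cohort generator** with lognormal baselines, mean-scaled
  visit noise whose SD is σ<sub>w</sub>·exp(κ·b<sub>i</sub>) (κ = 0: stable;
  κ > 0: responsive), multiplicative technical noise, and a tunable shared
  fraction of baseline variance within sibling families — plus a ground-truth
  manifest, so every estimator above is verified by parameter recovery.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each script
reads/writes under `results/`. End to end on the default synthetic study
(43 individuals × 4 quarterly visits × 35 subsets, 37 sibling families):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_variance.R
Rscript analysis/03_permutation.R
Rscript analysis/04_fluctuation.R
Rscript analysis/05_multivariate.R
Rscript analysis/06_siblings.R
```

which prints, among other lines:

```
median prop_within across 35 retained subsets: 0.27 (most variance sits between individuals)
within ~ between regression: slope 0.34, adjusted R^2 0.84, t = 13.6 (p = 4.1e-15)
35/35 subsets show between-individual variance exceeding within (q < 0.05, B = 999)
8/35 subsets show positive mean-variance coupling (p < 0.05):
  b1, cd4_emra, cd8_emra, gd_t, mono_inflammatory, plasmablast, plasmablast_iga, plasmablast_igg_syn
rank concordance of between-individual variance with coupling strength: rho = 0.65 (p = 2.1e-05)
first two PCs explain 13.9% of variance: individuals do not separate into discrete immunotype clusters
10/35 subsets are more concordant in siblings than in unrelated pairs (q < 0.05)
```

Reading: individual identity dominates temporal noise for every subset
(prop<sub>w</sub> ≈ 0.27, permutation q < 0.05 throughout), within- and
between-individual variance track each other linearly across subsets
(R² = 0.84), exactly the eight subsets generated as environmentally responsive
(κ = 1) are detected by mean–variance coupling, and sibling concordance
appears predominantly in stable (κ = 0) subsets. The same machinery accepts
real data via `read_observations()` / `read_replicates()` / `read_siblings()`
(CSV schemas documented in `?read_observations`), and `run_pipeline()` chains
every stage into a reproducible output bundle with a seed- and config-stamped
`summary.json`.

Equivalent interactive use:

```r
library(cytomevar)
cfg  <- generator_config(seed = 42)
obs  <- generate_cohort(cfg)$observations
summ <- variance_summary(obs, generate_replicates(cfg)$replicates)
regress_within_on_between(summ)
```

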