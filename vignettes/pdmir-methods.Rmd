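---
title: "Methods: two-phase plasma miRNA biomarker analysis for PD dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase plasma miRNA biomarker analysis for PD dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pdmir` implements a two-phase analysis for circulating plasma miRNA
biomarkers of cognitive decline in Parkinson's disease (PD): a *discovery*
phase that screens a supersaturated small-RNA-seq count matrix for
group-discriminative miRNAs, and a *validation* phase that quantifies a
candidate miRNA by droplet digital PCR (ddPCR) and evaluates it as a
predictor of PD dementia. This vignette documents the models, the tunable
parameters, the synthetic-data generator, and the numerical choices the
package makes where the underlying methods leave room.

## Study groups

Subjects fall into four groups by the Montreal Cognitive Assessment (MoCA,
0–30): healthy controls (HC) and PD with no dementia (PDND) at MoCA ≥ 26,
PD with mild cognitive impairment (PD-MCI) at 22–25, and PD dementia (PDD)
at ≤ 21. `dementia_label()` encodes the PDD cut (≤ 21) for the predictive
models.

## Discovery phase

### Normalization and preprocessing

Raw counts (miRNA × sample) may contain *missing* entries — miRNAs absent
from a sample's sequencing output — which `impute_missing()` sets to zero
before normalization, keeping the distinction between "not observed" and
"observed zero" explicit in the data representation until this point.

Between-sample normalization uses the trimmed mean of M-values (TMM):
per-sample scaling factors from a precision-weighted trimmed mean of
per-miRNA log2 expression ratios against a reference sample. The
computation is delegated to edgeR's canonical implementation with its
standard conventions, which `tmm_factors()` pins down explicitly because
the method itself leaves them open:

* trim fractions: 30% on M-values (log ratios), 5% on A-values (average
  log abundance);
* weights: inverse asymptotic (delta-method) variance of M;
* reference sample: the one whose upper quartile of counts-per-million is
  closest to the mean upper quartile;
* factors rescaled to geometric mean 1.

The test suite re-evaluates the published formula by hand on a toy matrix
and requires agreement to 1e-10, so these conventions are locked by test
rather than by trust in the dependency.

Expression values are `log2(CPM + 1)` on the TMM-effective library
(`normalize_log2()`). The +1 pseudocount avoids −∞ at zero counts; it is
the only transform parameter and is fixed rather than exposed, because
every downstream statistic is either rank-based or compares values on a
common scale.

`trim_low_expressed()` removes the union of the per-batch bottom deciles,
ranking miRNAs within each batch by their mean normalized value — the
simplest batch-local summary of "lowest expressed". `batch_adjust()` then
removes a per-miRNA location shift per batch (each batch is mean-centered
and moved to the pooled mean). A full surrogate-variable analysis is out
of scope here; the location-only adjustment matches the generator's batch
model exactly (see below), so within this package's testable world the
substitute is exact. On real data with structured (non-location) batch
effects it is weaker, and that is a stated limitation.

The group fold change (`fold_change()`) is the log2 ratio of *linear-scale*
group means (2^value − 1, i.e. CPM), case over control — the literal
"log2 of ratio of means" form, not a mean of logs. Whether the original
analysis took means on raw, CPM or TMM scale is not recoverable from its
description; the CPM choice is recorded here and is the package default.

### The Dantzig-type selector

With ~2600 features and ~60 samples per contrast the design is
supersaturated, and the selector of choice is an L1-minimization under a
score-band constraint (a Dantzig selector applied to the centered binary
response):

$$\min_\beta \|\beta\|_1 \quad \text{s.t.} \quad
  \|X^\top (y_c - X\beta)\|_\infty \le \delta$$

where `X` is the standardized expression matrix (columns mean 0, sd 1,
denominator n−1) and `y_c = y − mean(y)` the centered 0/1 group response.
The linear (rather than linearized-logistic) constraint is used because
the scheme standardizes X, centers Y and bounds its tuning grid by
max|XᵀY| — exactly the quantity at which the *linear* Dantzig solution
degenerates to zero; the logistic model enters only as the per-δ
classifier in cross-validation and as the final reporting model.

**Solver.** The program is solved as an LP in the split variables (β, u)
with a Mehrotra-style primal-dual interior-point method written for this
package. The normal equations are reduced by block elimination to a Schur
complement of the form `diag(F) + X'KX` with K an n×n positive
semidefinite kernel; a symmetric Woodbury factorization (through the
eigendecomposition of K) turns each Newton step into O(n²p) work, so
p = 500–2600 instances solve in tens of milliseconds. Convergence targets
a relative residual of 1e-9 with an acceptance fallback of 1e-5 when the
late-stage Newton systems become too ill-conditioned to improve further;
a closed-form feasibility polish (a minimal move toward the minimum-norm
least-squares solution, whose score residual is exactly zero) guarantees
the returned coefficients satisfy the score band. At δ ≥ max|Xᵀy_c| the
zero solution is provably optimal and is returned exactly.

**Activity classification.** Interior-point methods return the analytic
center of the optimal face. When the optimum is degenerate (routine in
supersaturated designs) this smears tiny coefficient mass — observed
around 1e-7 — across features that a vertex solution would set exactly to
zero, while genuine coefficients just before their shrink point sit near
(grid step)/(n−1) ≈ 1e-2. A purely absolute activity tolerance therefore
misclassifies the smear. A feature counts as active at δ when
`|β| > max(1e-8, 1e-3 × max|β(δ)|)`: the absolute floor keeps exact zeros
exact, the relative term removes solver smear, and the two regimes are
separated by several orders of magnitude at every problem size exercised
here.

**Grid, tuning and ranking.** The tuning grid is 15 uniformly spaced
points on (0, δ_max], δ_max = max|Xᵀy_c|; δ = 0 is excluded (degenerate)
and δ_max included, so every grid point is feasible. `cv_tune()` runs
stratified 5-fold cross-validation: per fold and δ, the selector runs on
the training rows (response recentered within the fold; the grid itself is
fixed from the full data), a logistic regression on the selected features
— stabilized with a tiny ridge (1e-6) to survive perfect separation on
small folds — scores the held-out rows, and the per-δ AUCs are averaged.
A fold with no selected feature contributes AUC 0.5. The best δ maximizes
mean AUC, ties resolved toward the larger δ (stronger shrinkage).
Stratification is a package choice: at 23 subjects per class, unstratified
folds risk single-class test sets. `final_selection()` recomputes the path
on [best δ, δ_max] and reports the features active at the best δ, ordered
by shrink-to-zero position: the last feature to leave the active set is
the most important, ties broken by |β| at the tied δ, then by the marginal
score |Xᵀy_c| — a deterministic rule chosen so the ranking is
reproducible.

One property worth knowing: on synthetic data with several planted
features of equal modest effect, cross-validation often tunes to a very
sparse δ (a single dominant feature generalizes best), so the candidate
list can be much shorter than the number of planted features. The
parameter-recovery analyses therefore read recovery off the top of the
shrink-to-zero ranking along the path, which is the ranking semantics of
the selector's solution-path plot, while the tuned candidate list remains
the primary reported output.

## Validation phase

### ddPCR quantification

Each well partitions the diluted sample into ~0.85 nL droplets; template
molecules land in droplets as a Poisson process, so with k positive out of
N droplets the undiluted concentration is

$$c = \frac{-\ln(1 - k/N)}{V_d} \cdot D$$

(`concentration()`), with D the dilution (1:10 for the target miR-203a-3p,
1:320 for the abundant reference miR-16-5p). Saturated wells (k = N) carry
no finite estimate and error out. QC (`qc_pass()`) requires more than
10,000 accepted droplets and more than 3 positives; the thresholds are
applied to *droplet counts* — 10,000 is the conventional accepted-droplet
floor — with a configuration switch to apply them to concentrations
instead, since the printed units in protocols of this kind are sometimes
ambiguous. Failing wells are flagged, never silently dropped.

The per-subject biomarker is the ratio of back-diluted concentrations,
target over reference (`sample_ratios()`); the ratio is invariant to
rescaling both dilutions. The reference/spike-in ratio (miR-16-5p /
UniSp6) should not differ between groups if RNA extraction efficiency is
uniform; `extraction_check()` tests this by Kruskal-Wallis and warns at
p < 0.05.

Outliers are flagged within each group by the 1.5×IQR fence rule
(`iqr_outliers()`), with quartiles from linear-interpolation quantiles
(R type 7) — the quantile convention is a recorded choice, as GUI
statistics packages differ here.

### Group comparison and correlation

`kruskal_wallis()` (via the standard tie-corrected rank statistic) and
`dunn_posthoc()` compare the ratio across groups. Dunn's z uses the joint
mid-ranks with the tie term Σ(t³−t)/(12(N−1)); adjusted p-values are
multiply-by-m Bonferroni capped at 1, displayed as "> 0.9999" at the cap —
the reporting convention of common GUI software — with Holm available
behind a flag. `spearman_cor()` is mid-rank Pearson with the two-sided t
approximation on n−2 df (appropriate at the n ≈ 90 used here; |r| = 1
maps to p = 0). `domain_correlation_table()` correlates the ratio with the
MoCA total and its seven domains within the PD patients, unadjusted for
multiplicity, matching the tabular presentation convention for this kind
of exploratory correlation screen.

### Predictive models

Within PD patients, dementia (MoCA ≤ 21) is modelled by logistic
regression. `reduce_by_aic()` fits **all** non-empty subsets of the six
candidate predictors (age, sex, onset age, education, UPDRS III, ratio) —
exhaustive search beats stepwise and costs nothing at 63 subsets — and
returns the smallest-AIC model, ties toward fewer predictors then
lexicographic. `model_comparison_table()` evaluates seven fixed variable
sets (ratio, age, UPDRS III and their combinations) out of sample:
training on a stratified 70% split, ROC on the held-out 30%, with the
operating point maximizing sensitivity + specificity (ties toward higher
specificity, then the higher threshold — fixed for determinism) and
stratified percentile bootstrap confidence intervals (B = 2000; class
stratification means no resample is ever single-class). Cross-validation
on the training side is used only as a stability check; final coefficients
come from the full training split. Predictors enter unstandardized, as
coefficients are not compared across predictors.

## Power analysis

`anova_power()` evaluates the fixed-effects one-way ANOVA power from the
noncentral F distribution with df (k−1, N−k) and noncentrality λ = f²·N —
the total-sample-size convention for Cohen's f used by standard a-priori
software; group balance does not enter the formula. `min_total_n()`
searches the smallest N meeting a target power; at f = 0.5, α = 0.05,
power 0.8, k = 4 it returns 48 (power 0.803 at 48, 0.793 at 47).

## The synthetic-data generator

The generator exists so that every stage is exercisable without patient
data; its defaults are the study conditions, fixed once.

**Discovery** (`discovery_design()`): 40/37/23/23 subjects
(HC/PDND/PD-MCI/PDD), 2600 miRNAs, two sequencing batches of 53 and 70
(the study's 123 subjects split in proportion to its two runs). Baseline
abundances are log-normal (sdlog 2 — a few miRNAs dominate, as in plasma),
library sizes uniform on 0.8–2 million reads (plasma small-RNA depth after
deduplication), counts negative-binomial with dispersion 0.3 (typical
between-subject biological variability), a per-batch per-miRNA
multiplicative log2 bias with SD 0.3 (location-only — matching the
location-only adjustment downstream), 2% of entries missing, and planted
log2 mean shifts on designated miRNAs between a designated group pair.

**Validation** (`validation_design()`): 30 subjects per group. True
ratios are drawn from a per-group lognormal matched by moments to the
published group means and SDs — lognormal because ratios are positive and
right-skewed, and the PDD SD is ~60% of its mean, which a
normal-truncated-at-zero cannot accommodate; the distributional family is
a modelling choice, not an inference about the real cohort. The reference
concentration is uniform on 2×10⁴–2×10⁵ copies/µL (so that both assays
land in the informative range of droplet counts at their dilutions), the
target concentration is ratio × reference, and wells are simulated as
binomial droplet occupancy — the exact inverse of the Poisson
quantification. Covariates follow the published group summaries: mean/SD
variables as rounded normals; median/IQR scale scores as normals with
sd = IQR/1.349, rounded and clipped to the scale's legal range; MoCA
totals additionally clipped to the group's diagnostic band. Domain scores
allocate the total deficit by sampling without replacement across the
seven domains (maxima 5/3/6/3/2/5/6), so domains always sum to the total
and respect their maxima. The UniSp6 spike-in is lognormal with 10% CV
around 5×10⁴ copies/µL — uniform extraction efficiency by construction.

What the generator does *not* emulate: sequencing adapter/UMI structure,
non-location batch effects, miRNA-miRNA correlation, covariate-ratio
dependence within groups (the ratio–MoCA association arises only through
group membership), ddPCR rain or misclassified droplets. Passing tests
therefore demonstrate correctness of the analysis machinery under the
stated statistical model, not robustness to those real-data features.

## Problem sizes and determinism

The test suite runs the selector's parameter-recovery study at p = 500
features (20 simulated cohorts of 37 + 23 subjects, the discovery contrast
size), the omnibus-test level check at 2000 simulations of 4×30, the
bootstrap coverage check at 500 replications of B = 2000, and the
validation directional check at 100 simulated cohorts; these sizes give
stable Monte-Carlo estimates while keeping a full run in minutes. A
p = 2600 discovery run is exercised by the analysis scripts. Every
stochastic step takes an explicit integer seed; a single global seed fans
out to stage seeds through a fixed arithmetic derivation
(`derive_seed()`), so stages can be rerun in isolation and identical
seeds reproduce every output exactly.

## Known limitations

* The batch adjustment is location-only; structured batch effects in real
  data call for surrogate-variable methods outside this package's scope.
* The selector's constraint is the linear Dantzig form on the centered
  binary response; a linearized logistic-score constraint is a plausible
  alternative reading of the underlying scheme and is not implemented.
* Whether the original 5-fold CV was stratified, and how mean-AUC ties
  were broken, is not recoverable; both conventions here are fixed,
  documented choices.
* The ddPCR model treats droplet classification as given; fluorescence
  thresholding ("rain") is upstream of this package.
* Printed cohort-level results (the six-candidate list, the published
  group differences, correlations and AUCs) are not reproducible from
  synthetic data; the package reproduces *procedures* and
  properties, plus the one analytic printed number (the sample-size
  requirement of 48).
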