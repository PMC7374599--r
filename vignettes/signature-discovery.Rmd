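---
title: "Discovering cross-compartment and temporal proteomic signatures of disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cross-compartment and temporal proteomic signatures of disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsig)
```

## The problem

Progressive fibrotic lung disease is heterogeneous: over an 80-week
follow-up some patients deteriorate (death, transplant, acute
exacerbation, or a large drop in FVC or DLCO) while others remain stable,
and single circulating biomarkers have repeatedly failed to validate as
predictors of which path a patient will take. The working hypothesis
behind this package is that progression is driven by dysregulated
*networks* of proteins spanning tissue compartments, so the unit of
analysis should be a multivariate signature: a small set of co-varying
blood and bronchoalveolar-lavage (BAL) proteins whose joint expression
separates progressors from non-progressors, and whose temporal behaviour
differs between the groups.

`progsig` implements that analysis as a chain of small, testable
operations: read/impute/normalise → outlier pruning → univariate volcano
→ penalised signature selection → PLS discriminant analysis →
classifier comparison → clustering and correlation networks → trajectory
analysis. A synthetic cohort generator with planted ground truth sits at
the front so that every downstream stage can be validated quantitatively,
which is the only honest option when the motivating study's cohort
measurements are not packaged with the method.

## Preprocessing rules

**Below-detection imputation.** Multiplexed BAL immunoassays report a
standard-curve detection floor; censored cells are set to one half of the
*lowest* minimum detectable concentration across all analytes (a single
global floor). `impute_lod()` applies exactly this rule; the LOD mask is
retained so provenance is never lost.

**Total-protein normalisation.** Lavage dilution varies between
procedures, so each BAL measurement is divided by its sample's total
protein (`normalize_total_protein()`); units become analyte per total
protein. Blood tables are refused — the transform is only meaningful for
lavage fluid.

**Merging.** `merge_compartments()` intersects subjects, concatenates
analyte columns with compartment tags, and keeps values bit-exact; blood
and BAL analytes enter all later scaling identically.

**Autoscaling.** Every analyte is mean-centred and scaled to unit
standard deviation (n−1 denominator). Scaling parameters are stored and
re-applied to held-out folds so cross-validation never leaks test-set
information. Zero-variance analytes either abort (default) or are dropped
with a warning (`on_zero_variance = "drop"`), which is the pipeline
behaviour.

**Negative-driver pruning.** A PCA model retaining the smallest number of
components A reaching 90% cumulative variance (configurable
`var_fraction`; the component cap is n−2) scores each sample with
Hotelling's T² in score space, divided by the 95% F-based confidence
limit. "Reduced T² > 5" therefore means *five times the 95% limit*, the
convention of the chemometrics toolboxes that report a "reduced"
statistic; the raw T² would flag most samples at any fixed small
threshold. The loop removes the single worst sample above 5 and refits
until clean, and aborts if it would remove more than half the cohort. A
consequence of this normalisation worth knowing: for a training sample,
T² ≤ A(n−1), so the reduced score is bounded by
n(n−A)/((n+1)·F₀.₉₅(A, n−A)) — a sample displaced along a single
principal direction in a small matrix (say 20 × 5) mathematically cannot
exceed 5, however extreme. Samples that do exceed 5 are those that
dominate the retained variance structure as a whole (e.g. multiplicative
shifts across many analytes when A is small), and those are exactly what
the procedure removes in our tests.

## Signature selection

`lasso_fit()` minimises (1/2n)‖y − Xβ‖² + λ‖β‖₁ by cyclic coordinate
descent with soft-thresholding, warm starts along a decreasing λ
sequence, and an active-set strategy (full KKT-checking sweeps alternate
with cheap sweeps over the nonzero set). The class is coded 0/1 (visits
0/1/2 for the temporal signature) and fitted by least squares, not
logistic regression — the convention of the toolbox lineage this
reproduces. Convergence is declared when the largest per-cycle
coefficient change drops below 1e−9; the suite verifies ≤ 1e−6 agreement
with an exact sign-pattern enumeration oracle, and with `glmnet` on
larger designs.

`lasso_cv()` builds a 100-point geometric grid from λ_max (the smallest
all-zero penalty, max|Xᵀy|/n) down to 10⁻³ λ_max, estimates mean squared
prediction error by seeded *stratified* k-fold cross-validation (k = 10
default; stratification keeps every class/visit level in every training
fold, and falls back to plain randomisation for continuous responses),
and refits on all data at the error-minimising penalty. The minimum-MSE
rule — not the 1-SE rule — is deliberate, matching the stated procedure
of the source analyses; its consequences under the null are discussed
under *Known limitations*. Fold paths use a relaxed 1e−6 tolerance (the
CV error surface does not need full precision); the final refit uses the
default. An all-zero solution raises an informative error unless
`allow_empty = TRUE`, in which case the empty signature is returned and
downstream code may interpret it as "no signal found".

`vip_select()` offers the small-panel alternative: analytes whose VIP
score in a fitted PLS-DA model reaches 1 (the mean-square value).

## PLS-DA

`fit_plsda()` is NIPALS PLS1 on the centred class coding: unit-norm
weights w ∝ Xᵀy, scores t = Xw, X-loadings p = Xᵀt/tᵀt, Y-loading
q = yᵀt/tᵀt, with X and y deflated per latent variable. Per-LV explained
X-variance and Y sum of squares are stored; VIP scores follow
VIPⱼ = √(p Σₐ SSYₐ wⱼₐ² / Σₐ SSYₐ), so Σ VIP² = p exactly (an identity
the suite asserts to 1e−8 on every fitted model). At full rank the fit
reproduces ordinary least squares; on small matrices the scores and
weights match an eigen-decomposition reference to 1e−8 up to sign.

**Orthogonalization.** For interpretability the score space is rotated
post hoc so LV1 is proportional to the fitted response: all
class-predictive variation concentrates on LV1, the remaining components
carry Y-uncorrelated variation, and fitted values, predictions and VIP
scores are unchanged (the rotation spans the same score space). The sign
convention puts the class coded 0 — non-progressors — on positive LV1
scores, so progressor-elevated proteins load negative.

**Classification and validation.** The continuous prediction is
thresholded at the class-code midpoint, ties to the higher code (the
simplest deterministic rule; the original toolbox's probabilistic
threshold is unpublished). `cross_validate()` recomputes *everything*
per outer fold — autoscaling, LV-count choice by an inner stratified CV
(misclassification-minimising, ties toward fewer LVs, default cap 10)
and the fit — so reported CV accuracy carries no selection optimism from
scaling or model-size choices; on label-permuted data it sits at the
majority-class rate. Display models use 2 LVs.

## Comparing classifiers

Matched calibration states (each patient correct/incorrect under each
model) are compared with Cochran's Q; with two models Q reduces exactly
to the uncorrected McNemar χ² = (b−c)²/(b+c). Post hoc McNemar tests use
the exact two-tailed binomial p when b + c < 25 and the
continuity-corrected χ² otherwise, Bonferroni-adjusted across pairs
("adjusted p" is otherwise unspecified in the source procedure; the most
conservative standard choice is used). When every subject is concordant
the Q denominator vanishes — but then the column totals are necessarily
equal, so the result is reported as Q = 0, p = 1 with a
`no_discordance` flag, and the post hoc test is inapplicable (a
situation the motivating study itself encountered when two models
classified everyone correctly). Per-fold CV accuracies are compared by
one-way ANOVA with Tukey HSD; folds share training data, so treating
them as independent replicates is anticonservative — this is documented
and retained because it is the stated procedure being reproduced.

## Clustering and networks

`hcluster()` uses average (UPGMA) linkage on the correlation distance
d = 1 − r between sample profiles over the signature (1 − r rather than
1 − |r|: anticorrelated profiles are dissimilar in the heatmap
convention). The clustering is unsupervised; "supervised" evaluation
means the known labels score the cut afterwards, each flat cluster
taking its majority label. Both a 2-cluster and a 4-cluster cut are
reported, since the published misclassification count could have come
from either reading of the dendrogram.

`corr_network()` computes all pairwise Pearson correlations within one
group over the signature, keeps edges with raw p < 0.05 (the t transform
on n−2 df — the identical code path as `pearson()`, so edge p-values
match it exactly; no multiplicity correction, by the source convention),
and flags hubs at degree ≥ 4. `compare_networks()` reports edge and hub
counts and a pooled two-sample t-test on the absolute correlations of
retained edges — the "fewer but stronger non-progressor correlations"
contrast.

## Trajectories

`temporal_signature()` pools one group's observations across visits,
codes the visits ordinally (0/1/2 — a deliberate choice; the source says
only that the selection "differentiated the three collection time
points", and ordinal coding is the minimal encoding that respects their
order), and runs `lasso_cv()`. `trajectory_pca()` autoscales the pooled
signature matrix and fits an ordinary PCA (pooled fit, the natural
reading of a trajectory model; the per-observation scores are grouped by
visit). `pc1_anova()` runs the one-way ANOVA with Tukey HSD across
visits, treating observations as independent — within-subject
correlation is ignored, faithfully reproducing the stated procedure; a
repeated-measures variant is explicitly out of scope. `kde_pc1()`
summarises the per-visit PC1 score distributions with Gaussian kernels
at the normal-reference bandwidth h = σ̂(4/(3n))^(1/5) on a shared grid
(all scores ± 3h), each density integrating to 1 within 1e−3.

## The synthetic cohort generator

`generate_cohort()` draws positive, right-skewed concentrations: each
analyte gets a log-normal baseline (median 100, log-SD 1.5 — spanning
the orders of magnitude typical of mixed cytokine/protein panels) and
multiplicative log-normal noise with 15–35% CV, the realistic range for
multiplexed immunoassays. All planted effects act on the latent
standardised scale:

* **Signature.** `k_signature` analytes, allocated between compartments
  proportionally (at least one BAL analyte when the signature has room),
  are shifted ± `effect_size`/2 per group (sign per analyte), giving a
  between-group difference of `effect_size` within-group SDs at every
  visit.
* **Subgroups.** Progressors are split into `n_subgroups` subgroups, each
  with a disjoint block of `subgroup_block_size` analytes elevated by
  `subgroup_effect` (default 2) only within that subgroup — heterogeneity
  that clustering can be tested against independently of classification,
  which is why the blocks are disjoint from the signature.
* **Correlation structure.** Non-progressor signature analytes share
  small latent factors (`nonprog_factor_size` = 4) with loading
  √`corr_strong`; progressor signature analytes share one broad factor
  with loading √`corr_weak` — few strong correlations vs many weak ones.
  Factor values are drawn *once per subject and persist across visits*:
  co-regulation is a property of the subject, and visit-level factor
  draws would create spurious batch-like temporal structure in a group
  with no planted drift. The multiplicative transform barely attenuates
  the targets (latent 0.3 realises as ≈ 0.29 at 25% CV). Defaults are
  `corr_strong` = 0.6, `corr_weak` = 0.2 — chosen so that the generator
  simultaneously exhibits its two reference regimes: LASSO can recover a
  20-analyte signature at effect 1.5 from 300 + 10 analytes with 25
  subjects per group, while explicit 0.8/0.3 settings (used in the
  network tests) produce the sparse-strong vs dense-weak contrast.
* **Drift.** `n_drift` blood analytes shift by `temporal_drift` per
  visit index (0, 1, 2), in progressors only, with a random sign per
  analyte — linear drift places the week-48 centroid between the
  endpoints, the qualitative pattern the trajectory analysis looks for.
* **Censoring.** Each BAL analyte's values below its empirical
  `lod_quantile` quantile are masked; the threshold is recorded as the
  analyte's minimum detectable concentration, and the exporter writes
  the sentinel token `"<LOD"`.

Default dimensions mirror the motivating study: 34 + 25 subjects, 1,129
blood analytes at weeks 0/48/80, 29 BAL analytes at week 0, a 54-analyte
planted signature; the planted effect sizes themselves are *not*
estimates of any real cohort (the study reports none in standardised
units) — they are tunable study conditions.

What the generator does **not** emulate: assay-specific artifacts
(aptamer cross-reactivity, plate/batch effects), missing visits,
subject-level covariates, non-linear temporal shapes, and correlation
among non-signature analytes. Passing tests therefore demonstrate that
the pipeline recovers the structures it claims to recover under a clean
factor model — not that any particular real cohort satisfies those
assumptions.

## Validation strategy and problem sizes

Every non-trivial computation is checked against an independent route:
coordinate descent against exhaustive KKT sign-pattern enumeration (and
`glmnet`); NIPALS against an eigen-decomposition PLS and against OLS at
full rank; VIP against its algebraic identity; McNemar against binomial
enumeration; ANOVA/Tukey against explicit sums-of-squares and
studentized-range formulas; ROC against `pROC`. Property-based tests run
the full pipeline on generated cohorts: planted-signature recovery
(25/group, 300 blood analytes, 20 seeds), separable-cohort classification
(30/group, effect 3, 20 seeds), network contrast (30/20, signature 30,
50 seeds), subgroup clustering (30/20, three 6-analyte blocks, 20 seeds,
adjusted Rand ≥ 0.7), temporal contrast (15/group, 10 drift analytes, 50
seeds) and type-I calibration of the volcano tests, network edge rate and
PC1 ANOVA (100 seeds each, binomial 2-SE bands). These sizes keep the
whole suite to a few minutes while leaving the detection margins
comfortably away from chance.

## Numerical choices and degenerate inputs

Ties at the CV-error minimum go to the larger penalty (sparser model);
prediction ties at the class midpoint go to the higher-coded class;
orthogonalization of a 1-LV model is the identity with a warning;
constant analytes are excluded from networks with a warning and abort or
drop (caller's choice) in autoscaling; a group absent from a confusion
metric's denominator yields `NA` plus an `undefined` flag rather than a
silent zero; degenerate zero-variance ANOVA inputs are flagged rather
than returning spurious F values.

## Known limitations

* **Null-data behaviour of minimum-MSE selection.** Under the null (no
  drift), the error-minimising penalty keeps a handful of noise analytes
  in roughly 40% of seeds, and a PC1 ANOVA computed on the same
  observations that selected those analytes is anti-conservative —
  about half of those non-empty null signatures reach p < 0.05. The
  ANOVA itself is exactly calibrated (5/100 rejections on fixed,
  non-selected null analytes), and `glmnet`'s `lambda.min` selects
  equally often on identical nulls, so this is a property of the
  prescribed procedure (select and test on the same data under a
  minimum-MSE rule), not of the implementation. Consequently the
  full-pipeline contrast "temporal signal in progressors only" holds in
  ~76% of seeds rather than the ~90% one might hope for; a 1-SE penalty
  rule would largely repair it but would depart from the procedure this
  package reproduces.
* Treating CV folds as independent replicates (classifier ANOVA) and
  ignoring within-subject correlation (trajectory ANOVA) are faithful
  but statistically optimistic choices, retained deliberately.
* The reduced-T² pruning threshold of 5 is only attainable by samples
  that dominate the retained variance; in very high-dimensional tables
  (A large) the bound above means pruning is rare — consistent with its
  role as a guard against catastrophic drivers, not a general outlier
  filter.
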