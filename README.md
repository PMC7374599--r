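# progsig

Cross-tissue-compartment and temporal proteomic signature discovery for
progressive disease cohorts.

`progsig` implements a complete, tested pipeline for the kind of study in
which blood and bronchoalveolar-lavage (BAL) protein panels are measured in
a two-group cohort (progressors vs non-progressors of idiopathic pulmonary
fibrosis being the motivating case) at one or more visits, and the goal is
to find multivariate protein *signatures* — not single biomarkers — that
separate the groups and track disease over time. It is aimed at
computational biologists who want the whole chain (quality control, feature
selection, classification, comparison, network and trajectory analysis) as
composable R functions with a synthetic cohort generator for validating
every stage against planted ground truth.

## What it computes

* **Sample QC** — iterative pruning of "negative driver" samples by
  Hotelling's reduced T², the PCA score statistic
  T²ᵢ = Σₐ t²ᵢₐ/λₐ divided by its 95% confidence limit
  T²₉₅ = A(n−1)(n+1)/(n(n−A)) · F₀.₉₅(A, n−A); the sample with the largest
  reduced score > 5 is removed and the model refitted until none remains.
* **Volcano statistics** — per-analyte fold change (progressor mean /
  non-progressor mean), pooled two-sample t-tests, Bonferroni flags.
* **LASSO signature selection** — coordinate-descent minimisation of
  (1/2n)‖y − Xβ‖² + λ‖β‖₁ over a 100-point geometric λ grid with seeded,
  stratified 10-fold cross-validation; the error-minimising penalty defines
  the signature (compiled inner loop; exactness is tested against a
  KKT-enumeration oracle).
* **PLS-DA** — hand-written NIPALS PLS1 on the centred class coding, with
  O-PLS-style orthogonalization (all class-predictive variation rotated
  onto LV1), VIP scores (mean square exactly 1), calibration and
  cross-validated accuracy (scaling and LV count refitted inside every
  training fold), confusion metrics and ROC/AUC.
* **Classifier comparison** — Cochran's Q with exact/continuity-corrected
  McNemar post hoc tests on matched classification states; one-way ANOVA
  with Tukey HSD on per-fold CV accuracies.
* **Structure** — average-linkage hierarchical clustering on the Pearson
  correlation distance 1 − r, scored against known labels; per-group
  correlation networks over a signature (edges at p < 0.05, hubs at degree
  ≥ 4) and the "fewer but stronger" contrast between groups.
* **Trajectories** — LASSO signatures separating the visit sequence
  (weeks 0/48/80 coded 0/1/2), trajectory PCA, PC1 one-way ANOVA with
  Tukey HSD across visits, Gaussian kernel densities of PC1 scores with
  the normal-reference bandwidth h = σ̂(4/(3n))^(1/5).
* **Synthetic cohorts** — `generate_cohort()` plants a cross-compartment
  discriminative signature, progressor subgroup blocks, group-specific
  latent-factor correlation structure (sparse-strong in non-progressors,
  dense-weak in progressors), a progressor-only linear temporal drift, and
  limit-of-detection censoring of BAL values, all with recorded ground
  truth and full seed reproducibility.

## Worked example

```r
library(progsig)

cfg    <- cohort_config(n_prog = 20, n_nonprog = 15, p_blood = 120,
                        p_bal = 12, k_signature = 15, effect_size = 2,
                        seed = 42)
cohort <- generate_cohort(cfg)

# preprocessing: impute BAL values below detection at half the global
# minimum detectable concentration, normalise BAL to total protein, merge
# compartments at week 0, prune negative drivers
bal    <- normalize_total_protein(impute_lod(cohort$bal_table))
merged <- merge_compartments(cohort$blood_tables[["0"]], bal)
pruned <- prune_negative_drivers(merged)
pruned$report
#> outlier_report: no samples removed

vol <- volcano(pruned$table)
sum(vol$significant_05)
#> [1] 23

# LASSO signature on the autoscaled combined table
sc  <- autoscale(pruned$table, on_zero_variance = "drop")
y   <- ifelse(pruned$table$sample_meta$group == "progressor", 1, 0)
sig <- lasso_cv(sc$table$values, y, k = 10, seed = 42)
sig
#> progsig_signature (lasso_cv): 20 analyte(s)
#>   lambda = 0.02381
#>   top: blood_0047 (-0.147), blood_0101 (0.0977), blood_0120 (0.0616), ...
mean(cohort$truth$signature_analytes %in% sig$analyte_ids)
#> [1] 0.6666667

# PLS-DA on the signature: calibration and cross-validated accuracy
sig_tab <- subset_table(pruned$table, analytes = sig$analyte_ids)
sc_sig  <- autoscale(sig_tab)
fit <- fit_plsda(sc_sig$table, pruned$table$sample_meta$group, n_lv = 2,
                 scaling = sc_sig$params)
fit
#> pls_model: 2 LV(s), 20 analytes
#>   explained X-variance: 32.2%, 8.0%
#>   classes: non_progressor=0, progressor=1
cross_validate(sig_tab, pruned$table$sample_meta$group, k = 10, seed = 42)
#> cv_result: pooled accuracy 100.0% over 10 folds (sizes 3-4)

# group-wise correlation networks over the signature
np <- corr_network(pruned$table, sig, "non_progressor")
pg <- corr_network(pruned$table, sig, "progressor")
compare_networks(np, pg)[c("edge_count", "mean_abs_r", "p_value")]
#> $edge_count
#> non_progressor     progressor
#>             16             18
#> $mean_abs_r
#> non_progressor     progressor
#>      0.6584755      0.5219426
#> $p_value
#> [1] 4.561318e-05

# temporal signature and trajectory PCA in progressors
ts <- temporal_signature(cohort$blood_tables, "progressor", seed = 42)
tm <- trajectory_pca(cohort$blood_tables, ts, "progressor")
pc1_anova(tm)$tukey
#>   comparison     diff   p_adjusted
#> 1       48-0 3.119185 1.120781e-11
#> 2       80-0 5.714322 1.120781e-11
#> 3      80-48 2.595137 1.121137e-11
```

The planted two-SD signature is classified perfectly in 10-fold CV, the
non-progressor network shows fewer but stronger correlations than the
progressor network (mean |r| 0.66 vs 0.52, pooled t-test p ≈ 5 × 10⁻⁵),
and the planted one-SD-per-visit drift produces cleanly ordered visit
centroids on PC1 (all Tukey-adjusted p ≈ 10⁻¹¹).

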