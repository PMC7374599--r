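drift_cohort <- function(seed, temporal_drift = 1, n_prog = 20,
                         n_nonprog = 20) {
  generate_cohort(cohort_config(
    n_prog = n_prog, n_nonprog = n_nonprog, p_blood = 60, p_bal = 4,
    k_signature = 8, effect_size = 1.5, n_subgroups = 2,
    subgroup_block_size = 2, n_drift = 10, temporal_drift = temporal_drift,
    seed = seed))
}

test_that("temporal LASSO recovers planted drift analytes and is reproducible", {
  hits <- numeric(5)
  for (s in 1:5) {
    coh <- drift_cohort(700 + s)
    sig <- temporal_signature(coh$blood_tables, "progressor", seed = s)
    hits[s] <- mean(coh$truth$drift_analytes %in% sig$analyte_ids)
  }
  expect_gte(mean(hits >= 0.7), 0.8)
  coh <- drift_cohort(711)
  s1 <- temporal_signature(coh$blood_tables, "progressor", seed = 42)
  s2 <- temporal_signature(coh$blood_tables, "progressor", seed = 42)
  expect_identical(s1$analyte_ids, s2$analyte_ids)
  expect_identical(s1$weights, s2$weights)
  # no-drift group: empty or near-empty signature in most seeds
  small <- 0
  for (s in 1:5) {
    coh <- drift_cohort(720 + s)
    sig <- temporal_signature(coh$blood_tables, "non_progressor",
                              seed = s, allow_empty = TRUE)
    if (length(sig) <= 3) small <- small + 1
  }
  expect_gte(small, 3)
  expect_error(temporal_signature(coh$blood_tables[1], "progressor"),
               ">= 2 distinct time points")
})

test_that("trajectory PCA orders drifting time-point centroids monotonically", {
  coh <- drift_cohort(731)
  tm <- trajectory_pca(coh$blood_tables, coh$truth$drift_analytes,
                       "progressor")
  cent <- vapply(tm$per_time_pc1, mean, numeric(1))
  expect_identical(names(cent), c("0", "48", "80"))
  expect_true(all(diff(cent) > 0) || all(diff(cent) < 0))
  # week 48 falls between the endpoints
  expect_true(cent[["48"]] > min(cent) && cent[["48"]] < max(cent))
  # scores are centred per component
  expect_lt(max(abs(colMeans(tm$scores))), 1e-10)
  # explained variance fractions are nonincreasing and in (0, 1]
  ev <- tm$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(ev > 0 & ev <= 1))
  # null group: centroid spread within noise
  tm0 <- trajectory_pca(coh$blood_tables, coh$truth$drift_analytes,
                        "non_progressor")
  cent0 <- vapply(tm0$per_time_pc1, mean, numeric(1))
  pooled_sd <- sd(unlist(tm0$per_time_pc1))
  expect_lt(max(cent0) - min(cent0), pooled_sd)
  expect_error(trajectory_pca(coh$blood_tables, c("nope"), "progressor"),
               "missing")
})

test_that("PC1 ANOVA separates drifting progressors but not null groups", {
  coh <- drift_cohort(741)
  tm <- trajectory_pca(coh$blood_tables, coh$truth$drift_analytes,
                       "progressor")
  res <- pc1_anova(tm)
  expect_lt(res$anova_p, 1e-6)
  expect_true(all(c("48-0", "80-0", "80-48") %in% res$tukey$comparison))
  p_08 <- res$tukey$p_adjusted[res$tukey$comparison == "80-0"]
  expect_lt(p_08, 0.001)
  # identical distributions: F = 0 via copied scores
  tm_same <- tm
  tm_same$per_time_pc1 <- list("0" = tm$per_time_pc1[["0"]],
                               "48" = tm$per_time_pc1[["0"]],
                               "80" = tm$per_time_pc1[["0"]])
  res_same <- pc1_anova(tm_same)
  expect_equal(res_same$anova_f, 0, tolerance = 1e-12)
  expect_equal(res_same$anova_p, 1, tolerance = 1e-12)
  # type-I control on null (non-progressor) groups, scored on analytes with
  # no planted structure (independent across subjects and visits)
  rejections <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    coh_s <- generate_cohort(cohort_config(
      n_prog = 2, n_nonprog = 15, p_blood = 20, p_bal = 2, k_signature = 3,
      effect_size = 1, n_subgroups = 1, subgroup_block_size = 1,
      n_drift = 4, temporal_drift = 1, seed = 800 + s))
    tr <- coh_s$truth
    nulls <- setdiff(coh_s$blood_tables[["0"]]$analyte_meta$analyte_id,
                     c(tr$signature_analytes, unlist(tr$subgroup_analytes),
                       tr$drift_analytes))
    tm_s <- trajectory_pca(coh_s$blood_tables, nulls[1:6], "non_progressor")
    if (pc1_anova(tm_s)$anova_p < 0.05) rejections <- rejections + 1
  }
  se <- sqrt(0.05 * 0.95 / n_seeds)
  expect_lt(abs(rejections / n_seeds - 0.05), 2 * se + 0.05)
})

test_that("kernel densities integrate to one and match the normal reference", {
  coh <- drift_cohort(751)
  tm <- trajectory_pca(coh$blood_tables, coh$truth$drift_analytes,
                       "progressor")
  kd <- kde_pc1(tm)
  for (tw in names(kd)) {
    d <- kd[[tw]]
    expect_false(d$degenerate)
    integral <- sum(d$density) * diff(d$grid[1:2])
    expect_lt(abs(integral - 1), 1e-3)
    # bandwidth follows the normal-reference rule
    x <- tm$per_time_pc1[[tw]]
    expect_equal(d$bandwidth, sd(x) * (4 / (3 * length(x)))^(1 / 5))
  }
  # convergence: standard normal KDE at 0 approaches 1/sqrt(2*pi)
  set.seed(90)
  at_zero <- replicate(5, {
    z <- rnorm(1000)
    h <- sd(z) * (4 / (3 * 1000))^(1 / 5)
    density(z, bw = h, from = -0.001, to = 0.001, n = 3)$y[2]
  })
  expect_lt(abs(mean(at_zero) - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)), 0.1)
  # well-separated drift endpoints overlap little
  lo <- kd[["0"]]; hi <- kd[["80"]]
  overlap <- sum(pmin(lo$density, hi$density)) * diff(lo$grid[1:2])
  expect_lt(overlap, 0.5)
})
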