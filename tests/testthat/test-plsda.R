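test_that("NIPALS agrees with the eigen-decomposition reference up to sign", {
  for (s in 1:5) {
    set.seed(400 + s)
    X <- scale(matrix(rnorm(12 * 6), 12, 6))[, ]
    y <- rnorm(12)
    fit <- fit_plsda(X, y, n_lv = 3)
    ref <- pls_eigen_oracle(X, y, n_lv = 3)
    expect_equal_up_to_sign(fit$W, ref$W, 1e-8)
    expect_equal_up_to_sign(fit$P, ref$P, 1e-8)
    expect_equal_up_to_sign(fit$Tmat, ref$Tmat, 1e-8)
    expect_equal(unname(fit$b), ref$b, tolerance = 1e-8)
  }
})

test_that("PLS at full rank reproduces least squares", {
  set.seed(8)
  X <- scale(matrix(rnorm(9 * 6), 9, 6))[, ]
  y <- rnorm(9)
  fit <- fit_plsda(X, y, n_lv = 6)
  pred <- predict(fit, X)$score
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(unname(pred), unname(ols$fitted.values), tolerance = 1e-8)
})

test_that("model structure: orthogonal scores, unit weights, VIP identity", {
  set.seed(19)
  for (p in c(4, 15)) {
    sim <- make_shifted_matrix(n_per_group = 12, p = p, k = 2, delta = 1.5,
                               seed = p)
    X <- autoscale(sim$x)$table
    fit <- fit_plsda(X, sim$group, n_lv = 3)
    G <- crossprod(fit$Tmat)
    off <- abs(G[upper.tri(G)])
    expect_lt(max(off / sqrt(diag(G)[1] * diag(G)[2])), 1e-8)
    expect_equal(unname(colSums(fit$W^2)), rep(1, 3), tolerance = 1e-10)
    expect_equal(sum(fit$vip^2), p, tolerance = 1e-8)
    expect_true(all(fit$explained_x_variance >= 0))
    expect_lt(sum(fit$explained_x_variance), 1 + 1e-10)
  }
  # planted importance: only the shifted analytes should dominate
  sim <- make_shifted_matrix(n_per_group = 20, p = 10, k = 1, delta = 4,
                             seed = 3)
  fit <- fit_plsda(autoscale(sim$x)$table, sim$group, n_lv = 2)
  expect_equal(names(which.max(fit$vip)), "a01")
  expect_gt(fit$vip["a01"], 1)
  expect_true(all(fit$vip[-1] < fit$vip[1]))
})

test_that("separable univariate data classify perfectly with one LV", {
  x <- matrix(c(rnorm(10, -3), rnorm(10, 3)), 20, 1,
              dimnames = list(NULL, "a"))
  grp <- rep(c("non_progressor", "progressor"), each = 10)
  fit <- fit_plsda(autoscale(x)$table, grp, n_lv = 1)
  expect_equal(mean(predict(fit, autoscale(x)$table)$class == grp), 1)
})

test_that("label permutation collapses the explained class variance", {
  sim <- make_shifted_matrix(n_per_group = 15, p = 10, k = 3, delta = 2,
                             seed = 23)
  X <- autoscale(sim$x)$table
  fit <- fit_plsda(X, sim$group, n_lv = 1)
  r2_true <- fit$ssy[1] / sum((c(0, 1)[factor(sim$group)] - 0.5)^2)
  set.seed(71)
  r2_perm <- replicate(20, {
    f <- fit_plsda(X, sample(sim$group), n_lv = 1)
    f$ssy[1] / sum((c(0, 1)[factor(sim$group)] - 0.5)^2)
  })
  expect_gt(r2_true, max(r2_perm))
  expect_lt(mean(r2_perm), 0.5 * r2_true)
})

test_that("orthogonalization keeps predictions and concentrates class separation on LV1", {
  set.seed(31)
  for (s in 1:5) {
    sim <- make_shifted_matrix(n_per_group = 14, p = 12, k = 4, delta = 1.2,
                               seed = 500 + s)
    X <- autoscale(sim$x)$table
    fit <- fit_plsda(X, sim$group, n_lv = 3)
    ofit <- orthogonalize(fit)
    expect_equal(predict(ofit, X)$score, predict(fit, X)$score,
                 tolerance = 1e-10)
    expect_identical(predict(ofit, X)$class, predict(fit, X)$class)
    y01 <- as.numeric(factor(sim$group)) - 1
    expect_gte(abs(cor(ofit$Tmat[, 1], y01)) + 1e-12,
               abs(cor(fit$Tmat[, 1], y01)))
    # scores stay orthogonal after rotation
    G <- crossprod(ofit$Tmat)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    # orientation: class coded 0 (non_progressor) positive on LV1
    expect_gt(mean(ofit$Tmat[y01 == 0, 1]), 0)
    # orthogonal components are class-neutral: LV2 group means match
    expect_lt(abs(mean(ofit$Tmat[y01 == 0, 2]) - mean(ofit$Tmat[y01 == 1, 2])),
              3 * sd(ofit$Tmat[, 2]) / sqrt(length(y01) / 4))
  }
  one_lv <- fit_plsda(autoscale(make_shifted_matrix(seed = 2)$x)$table,
                      make_shifted_matrix(seed = 2)$group, n_lv = 1)
  expect_warning(orthogonalize(one_lv), "identity")
})

test_that("prediction uses the midpoint rule with ties to the higher code", {
  x <- matrix(c(-2, -1, 1, 2), 4, 1, dimnames = list(NULL, "a"))
  grp <- c("non_progressor", "non_progressor", "progressor", "progressor")
  sc <- autoscale(x)
  fit <- fit_plsda(sc$table, grp, n_lv = 1, scaling = sc$params)
  # raw newdata is scaled through the stored params inside predict
  pr <- predict(fit, x)
  expect_identical(pr$class,
                   c("non_progressor", "non_progressor", "progressor",
                     "progressor"))
  # construct a sample whose score is exactly the midpoint 0.5
  xm <- matrix(0, 1, 1, dimnames = list(NULL, "a"))
  pm <- predict(fit, xm)
  expect_equal(pm$score, 0.5, tolerance = 1e-12)
  expect_identical(pm$class, "progressor")  # higher-coded class wins ties
  # score is monotone along the discriminant direction
  grid <- matrix(seq(-3, 3, length.out = 11), ncol = 1,
                 dimnames = list(NULL, "a"))
  expect_true(all(diff(predict(fit, grid)$score) > 0))
  expect_error(predict(fit, matrix(1, 1, 1, dimnames = list(NULL, "zz"))),
               "analyte")
})

test_that("stratified cross-validation behaves on separable, null and sized designs", {
  # separable: near-perfect pooled accuracy
  sim <- make_shifted_matrix(n_per_group = 30, p = 10, k = 10, delta = 3,
                             seed = 61)
  cv <- cross_validate(sim$x, sim$group, k = 10, seed = 1)
  expect_gte(cv$pooled_cv_accuracy, 0.95)
  expect_equal(cv$pooled_cv_accuracy, mean(cv$per_sample_correct))
  # fold sizes for n = 59 are 5 or 6
  sim59 <- make_shifted_matrix(n_per_group = 30, p = 8, k = 2, delta = 1,
                               seed = 5)
  x59 <- sim59$x[1:59, ]; g59 <- sim59$group[1:59]
  cv59 <- cross_validate(x59, g59, k = 10, seed = 2, n_lv_max = 3)
  expect_true(all(table(cv59$fold_assignment) %in% 5:6))
  # permuted labels: accuracy near the majority-class rate
  set.seed(91)
  accs <- replicate(5, {
    g <- sample(sim$group)
    cross_validate(sim$x, g, k = 10, seed = 3, n_lv_max = 3)$pooled_cv_accuracy
  })
  expect_lt(mean(accs), 0.68)
  expect_identical(
    cross_validate(sim$x, sim$group, k = 10, seed = 9)$per_sample_prediction,
    cross_validate(sim$x, sim$group, k = 10, seed = 9)$per_sample_prediction
  )
})

test_that("classification metrics follow the confusion counts", {
  truth <- c(rep("pos", 4), rep("neg", 4))
  pred <- c("pos", "pos", "pos", "neg", "neg", "neg", "pos", "pos")
  m <- classification_metrics(pred, truth, positive_class = "pos")
  expect_equal(m$tp, 3); expect_equal(m$fn, 1)
  expect_equal(m$tn, 2); expect_equal(m$fp, 2)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$ppv, 0.6)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$accuracy, 5 / 8)
  perfect <- classification_metrics(truth, truth, "pos")
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv")]) == 1))
  flipped <- classification_metrics(ifelse(truth == "pos", "neg", "pos"),
                                    truth, "pos")
  expect_equal(flipped$sensitivity, 0)
  expect_equal(flipped$specificity, 0)
  # absent class: metric flagged undefined, not silently zero
  onecls <- classification_metrics(rep("pos", 3), rep("pos", 3), "pos")
  expect_true(is.na(onecls$specificity))
  expect_true("specificity" %in% onecls$undefined)
})

test_that("ROC curves sweep thresholds correctly", {
  truth <- c(rep("pos", 5), rep("neg", 5))
  perfect <- roc_curve(c(5:1, -(1:5)), truth, "pos")
  expect_equal(perfect$auc, 1)
  expect_true(all(diff(perfect$tpr) >= 0))
  expect_true(all(diff(perfect$fpr) >= 0))
  reversed <- roc_curve(-c(5:1, -(1:5)), truth, "pos")
  expect_equal(reversed$auc, 0)
  set.seed(17)
  scores <- rnorm(10)
  r <- roc_curve(scores, truth, "pos")
  expect_equal(roc_curve(-scores, truth, "pos")$auc, 1 - r$auc)
  # chance-level AUC for class-independent scores
  set.seed(33)
  aucs <- replicate(50, roc_curve(rnorm(40), rep(c("pos", "neg"), 20),
                                  "pos")$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_error(roc_curve(1:3, rep("pos", 3), "pos"), "both classes")
})

test_that("ROC AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  truth <- rep(c("pos", "neg"), each = 15)
  scores <- rnorm(30) + (truth == "pos")
  mine <- roc_curve(scores, truth, "pos")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("neg", "pos")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-10)
})
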