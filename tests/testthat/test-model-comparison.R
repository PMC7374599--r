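test_that("Cochran's Q handles identity, degeneracy and matches hand computation", {
  m <- cbind(a = c(1, 0, 1, 1, 0, 1), b = c(1, 0, 1, 1, 0, 1))
  res <- cochran_q(m)
  expect_equal(res$q_statistic, 0)
  expect_equal(res$p_value, 1)
  # all-concordant matrix: flagged, with the post hoc inapplicable
  conc <- cbind(c(1, 1, 0), c(1, 1, 0))
  expect_true(cochran_q(conc)$no_discordance)
  expect_equal(cochran_q(conc)$q_statistic, 0)
  # a matrix with discordant rows is not flagged
  expect_false(cochran_q(rbind(c(1, 0), c(0, 1), c(1, 1)))$no_discordance)
  # hand-worked 3-model, 6-subject instance:
  # rows: (1,1,0),(1,0,0),(1,1,1),(0,0,0),(1,0,1),(0,1,1)
  m3 <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0), c(1, 0, 1),
              c(0, 1, 1))
  # G = (4,3,3), L = (2,1,3,0,2,2); Q = 3*2*[(4-10/3)^2+2*(3-10/3)^2]
  #                                     / (3*10 - 22) = 6*(2/3)/8 = 0.5
  res3 <- cochran_q(m3)
  expect_equal(res3$q_statistic, 0.5)
  expect_equal(res3$df, 2)
  expect_equal(res3$p_value, pchisq(0.5, 2, lower.tail = FALSE))
  # invariance to row order and consistent relabeling of "correct"
  perm <- m3[sample(6), ]
  expect_equal(cochran_q(perm)$q_statistic, 0.5)
  expect_equal(cochran_q(1 - m3)$q_statistic, 0.5)
})

test_that("Q with two models equals the uncorrected McNemar chi-squared", {
  set.seed(12)
  for (i in 1:10) {
    m <- matrix(rbinom(40, 1, 0.6), 20, 2)
    b <- sum(m[, 1] == 1 & m[, 2] == 0)
    cc <- sum(m[, 1] == 0 & m[, 2] == 1)
    if (b + cc == 0) next
    expect_equal(cochran_q(m)$q_statistic, (b - cc)^2 / (b + cc),
                 tolerance = 1e-12)
  }
})

test_that("McNemar post hoc: exact binomial, corrected chi-squared, adjustment", {
  # b = 9, c = 1: exact two-tailed binomial p = 2 P(X <= 1 | 10, 1/2)
  m <- rbind(
    matrix(rep(c(1, 0), 9), ncol = 2, byrow = TRUE),   # 9 discordant: A only
    c(0, 1),                                           # 1 discordant: B only
    matrix(rep(c(1, 1), 5), ncol = 2, byrow = TRUE)    # concordant padding
  )
  colnames(m) <- c("A", "B")
  res <- mcnemar_posthoc(m)
  expect_equal(res$b, 9)
  expect_equal(res$c, 1)
  expect_equal(res$p_raw, 22 / 1024, tolerance = 1e-12)
  # enumeration oracle: sum the binomial tails explicitly
  exact <- 2 * sum(choose(10, 0:1)) / 2^10
  expect_equal(res$p_raw, exact)
  # b = 20, c = 5 switches to the continuity-corrected chi-squared
  m2 <- rbind(
    matrix(rep(c(1, 0), 20), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), 5), ncol = 2, byrow = TRUE)
  )
  res2 <- mcnemar_posthoc(m2)
  expect_equal((abs(20 - 5) - 1)^2 / 25, 7.84)
  expect_equal(res2$p_raw, pchisq(7.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res2$p_raw, 0.0051, tolerance = 1e-2)
  # no discordance: p = 1 with a note
  m3 <- cbind(c(1, 1, 0), c(1, 1, 0))
  res3 <- mcnemar_posthoc(m3)
  expect_equal(res3$p_raw, 1)
  expect_match(res3$note, "no discordance")
  # Bonferroni across the three pairs of a 3-model matrix
  m4 <- cbind(A = c(rep(1, 10), rep(0, 5)),
              B = c(rep(0, 10), rep(1, 5)),
              C = rep(1, 15))
  res4 <- mcnemar_posthoc(m4)
  expect_equal(nrow(res4), 3)
  expect_true(all(res4$p_adjusted >= res4$p_raw))
  expect_equal(res4$p_adjusted, pmin(1, res4$p_raw * 3))
})

test_that("exact McNemar keeps the null rejection rate at or below alpha", {
  # two equally accurate classifiers: discordance is symmetric Bernoulli
  set.seed(77)
  n_sims <- 200
  rej <- 0
  for (i in seq_len(n_sims)) {
    correct_a <- rbinom(30, 1, 0.8)
    correct_b <- rbinom(30, 1, 0.8)
    res <- mcnemar_posthoc(cbind(correct_a, correct_b))
    if (res$p_raw < 0.05) rej <- rej + 1
  }
  se <- sqrt(0.05 * 0.95 / n_sims)
  expect_lte(rej / n_sims, 0.05 + 2 * se)
})

test_that("fold-accuracy ANOVA with Tukey matches an independent computation", {
  acc <- list(m1 = c(0.8, 0.9, 1.0, 0.8, 0.9),
              m2 = c(0.6, 0.7, 0.6, 0.8, 0.7),
              m3 = c(0.9, 1.0, 0.9, 0.8, 1.0))
  res <- fold_accuracy_anova(acc)
  # independent one-way ANOVA from sums of squares
  all_v <- unlist(acc)
  grand <- mean(all_v)
  ss_between <- 5 * sum((vapply(acc, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(acc, function(v) sum((v - mean(v))^2), numeric(1)))
  f_ref <- (ss_between / 2) / (ss_within / 12)
  expect_equal(res$anova_f, f_ref, tolerance = 1e-10)
  expect_equal(res$anova_p, pf(f_ref, 2, 12, lower.tail = FALSE),
               tolerance = 1e-10)
  # Tukey adjusted p from the studentized range distribution
  mse <- ss_within / 12
  q12 <- abs(mean(acc$m1) - mean(acc$m2)) / sqrt(mse / 5)
  p12_ref <- ptukey(q12, nmeans = 3, df = 12, lower.tail = FALSE)
  row12 <- res$tukey[res$tukey$comparison %in% c("m2-m1", "m1-m2"), ]
  expect_equal(row12$p_adjusted, p12_ref, tolerance = 1e-8)
  # identical lists: F = 0, p = 1
  same <- list(a = c(0.8, 0.9, 0.7), b = c(0.8, 0.9, 0.7))
  res_same <- fold_accuracy_anova(same)
  expect_equal(res_same$anova_f, 0)
  expect_equal(res_same$anova_p, 1)
  # two models: F equals the squared pooled t statistic
  two <- list(a = c(0.8, 0.9, 1.0, 0.7), b = c(0.6, 0.7, 0.5, 0.8))
  tt <- two_sample_ttest(two$a, two$b)
  expect_equal(fold_accuracy_anova(two)$anova_f, tt$statistic^2,
               tolerance = 1e-10)
  # degenerate: all constant and equal
  expect_true(fold_accuracy_anova(list(a = c(1, 1), b = c(1, 1)))$degenerate)
  expect_error(fold_accuracy_anova(list(a = 1:3)), ">= 2 models")
  expect_error(fold_accuracy_anova(list(a = 1:3, b = 1:2)), "same number")
})
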