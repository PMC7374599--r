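#' Cochran's Q test on matched classification states
#'
#' Compares k >= 2 classifiers scored on the same subjects, each cell a
#' dichotomous correct/incorrect state. With column success totals
#' \eqn{G_j} and row success totals \eqn{L_i},
#' \deqn{Q = \frac{k (k-1) \sum_j (G_j - \bar G)^2}{k \sum_i L_i - \sum_i L_i^2}}
#' referred to a chi-squared distribution with k - 1 degrees of freedom.
#' Rows in which every model agrees (all correct or all incorrect)
#' contribute nothing to Q. If *all* rows are concordant the column totals
#' are necessarily equal, so the result is reported as Q = 0, p = 1 with
#' the `no_discordance` flag set (the post hoc test cannot be applied in
#' that situation).
#'
#' @param matrix logical or 0/1 matrix, subjects x models.
#' @return List with `q_statistic`, `p_value`, `df` and `no_discordance`.
#' @export
cochran_q <- function(matrix) {
  m <- .as_binary_matrix(matrix)
  k <- ncol(m); n <- nrow(m)
  if (k < 2) stop("need >= 2 models")
  if (n < 2) stop("need >= 2 subjects")
  L <- rowSums(m)
  G <- colSums(m)
  denom <- k * sum(L) - sum(L^2)
  if (denom == 0) {
    return(list(q_statistic = 0, p_value = 1, df = k - 1,
                no_discordance = TRUE))
  }
  q <- k * (k - 1) * sum((G - mean(G))^2) / denom
  list(q_statistic = q, p_value = pchisq(q, df = k - 1, lower.tail = FALSE),
       df = k - 1, no_discordance = FALSE)
}

.as_binary_matrix <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("classification matrix must have no missing cells")
  if (is.logical(m)) m <- m * 1L
  if (!all(m %in% c(0, 1))) stop("cells must be dichotomous (0/1)")
  m
}

#' Pairwise McNemar post hoc tests
#'
#' For every pair of models, counts the discordant subjects (`b`: first
#' model correct only, `c`: second model correct only) and tests b = c.
#' Small discordance (`b + c < exact_threshold`) uses the exact two-tailed
#' binomial test \eqn{p = 2 P(X \le \min(b, c) \mid n = b + c, 1/2)}
#' (clamped at 1); otherwise the continuity-corrected chi-squared
#' \eqn{(|b - c| - 1)^2 / (b + c)} on 1 df. P-values are adjusted across
#' pairs (Bonferroni by default). Pairs with no discordant subjects return
#' p = 1 with a note.
#'
#' @param matrix subjects x models dichotomous matrix (as [cochran_q()]).
#' @param adjust multiplicity adjustment across pairs (a [stats::p.adjust()]
#'   method; default `"bonferroni"`).
#' @param exact_threshold switch from exact binomial to corrected
#'   chi-squared at this many discordant pairs (default 25).
#' @return data.frame with one row per model pair: `model_a`, `model_b`,
#'   `b`, `c`, `p_raw`, `p_adjusted`, `note`.
#' @export
mcnemar_posthoc <- function(matrix, adjust = "bonferroni",
                            exact_threshold = 25) {
  m <- .as_binary_matrix(matrix)
  k <- ncol(m)
  if (k < 2) stop("need >= 2 models")
  if (is.null(colnames(m))) colnames(m) <- paste0("model_", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    a <- m[, ij[1]]; bcol <- m[, ij[2]]
    b <- sum(a == 1 & bcol == 0)
    cc <- sum(a == 0 & bcol == 1)
    if (b + cc == 0) {
      c(b = b, c = cc, p = 1, note = 1)
    } else if (b + cc < exact_threshold) {
      p <- min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
      c(b = b, c = cc, p = p, note = 0)
    } else {
      stat <- (abs(b - cc) - 1)^2 / (b + cc)
      c(b = b, c = cc, p = pchisq(stat, 1, lower.tail = FALSE), note = 0)
    }
  })
  out <- data.frame(
    model_a = colnames(m)[pairs[1, ]],
    model_b = colnames(m)[pairs[2, ]],
    b = res["b", ], c = res["c", ],
    p_raw = res["p", ],
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  out$note <- ifelse(res["note", ] == 1, "no discordance", "")
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD on per-fold CV accuracies
#'
#' Treats each model's k per-fold cross-validation accuracies as
#' replicates, tests the model effect with a standard one-way ANOVA, and
#' follows up with Tukey's honestly-significant-difference pairwise
#' comparisons (studentized-range adjusted p-values). Note that folds share
#' training data, so the independence assumption is optimistic; the
#' procedure is the conventional one for comparing fold-level accuracies
#' and is reported as such.
#'
#' @param accuracies named list of numeric vectors, one per model, all the
#'   same length (k folds).
#' @return List with `anova_f`, `anova_p`, `df`, `tukey` (data.frame of
#'   pairwise mean differences with adjusted p) and `degenerate` flag (set
#'   when every group has zero variance and equal means, where F is
#'   undefined).
#' @export
fold_accuracy_anova <- function(accuracies) {
  if (length(accuracies) < 2) stop("need >= 2 models")
  lens <- lengths(accuracies)
  if (length(unique(lens)) != 1 || lens[1] < 2)
    stop("each model needs the same number (>= 2) of fold accuracies")
  if (is.null(names(accuracies)))
    names(accuracies) <- paste0("model_", seq_along(accuracies))
  .oneway_tukey(accuracies)
}

# Shared one-way ANOVA + Tukey HSD over a named list of numeric vectors
# (also backs the trajectory PC1 test, where group sizes may differ).
.oneway_tukey <- function(groups) {
  lens <- lengths(groups)
  within_var <- vapply(groups, var, numeric(1))
  means <- vapply(groups, mean, numeric(1))
  if (all(within_var == 0) && all(means == means[1])) {
    return(list(anova_f = NA_real_, anova_p = NA_real_,
                df = c(length(groups) - 1, sum(lens) - length(groups)),
                tukey = NULL, degenerate = TRUE))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    level = factor(rep(names(groups), lens))
  )
  fit <- aov(value ~ level, data = df)
  ss <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$level
  tukey <- data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    p_adjusted = tk[, "p adj"],
    stringsAsFactors = FALSE
  )
  rownames(tukey) <- NULL
  list(anova_f = ss$`F value`[1], anova_p = ss$`Pr(>F)`[1],
       df = ss$Df, tukey = tukey, degenerate = FALSE)
}
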