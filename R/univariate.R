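#' Fold change between group means
#'
#' Ratio of the mean expression in the progressor group to the mean in the
#' non-progressor group, computed on raw (unscaled) concentrations. Values
#' above 1 indicate elevation in progressors.
#'
#' @param x_prog,y_nonprog numeric vectors of raw concentrations.
#' @return The ratio `mean(x_prog) / mean(y_nonprog)`.
#' @export
fold_change <- function(x_prog, y_nonprog) {
  if (length(x_prog) == 0 || length(y_nonprog) == 0)
    stop("both groups must be non-empty")
  m_y <- mean(y_nonprog)
  if (m_y == 0) stop("non-progressor mean is zero; fold change undefined")
  mean(x_prog) / m_y
}

#' Pooled-variance two-sample t-test
#'
#' Student's two-sample t with the pooled variance estimate and
#' `n1 + n2 - 2` degrees of freedom (two-tailed). A Welch-corrected variant
#' is available behind the `welch` switch. Groups whose pooled variance is
#' zero return `p = 1` when the means agree and raise an error otherwise.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param welch use the Welch (unequal-variance) correction instead of the
#'   pooled statistic. Default `FALSE`.
#' @return List with `statistic` (t), `p_value` (two-tailed) and `df`.
#' @export
two_sample_ttest <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 observations")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, p_value = 1, df = n1 + n2 - 2))
    stop("zero pooled variance with unequal means; t undefined")
  }
  if (welch) {
    ht <- t.test(x, y, var.equal = FALSE)
  } else {
    ht <- t.test(x, y, var.equal = TRUE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Bonferroni significance flags
#'
#' Flags each p-value significant iff `p < alpha / m`, with `m` the number
#' of tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error level (default 0.05).
#' @return Logical vector of flags.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p_values < alpha / length(p_values)
}

#' Pearson correlation with t-distribution p-value
#'
#' Sample correlation coefficient with the usual two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. The
#' identical formula is used for every network edge in [corr_network()], so
#' edge p-values and this function agree exactly.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return List with `r`, `p_value` and `n`.
#' @export
pearson <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0) stop("constant input; correlation undefined")
  r <- cor(x, y)
  list(r = r, p_value = .pearson_p(r, n), n = n)
}

# Two-tailed p for a Pearson r at sample size n (t transform, df = n - 2).
.pearson_p <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  2 * pt(tstat, df = n - 2, lower.tail = FALSE)
}

#' Volcano-plot statistics for every analyte
#'
#' Per-analyte fold change (progressor mean over non-progressor mean) and
#' pooled two-sample t-test on raw concentrations, with significance flags
#' at 0.05, 0.01 and the Bonferroni-corrected 0.05 level.
#'
#' @param table an [analyte_table()] (raw concentrations, imputed).
#' @param positive_group group label treated as the progressor/numerator
#'   group (default `"progressor"`).
#' @param welch passed to [two_sample_ttest()].
#' @return data.frame with columns `analyte_id`, `fold_change`, `t`,
#'   `p_value`, `significant_05`, `significant_01`,
#'   `significant_bonferroni`.
#' @export
volcano <- function(table, positive_group = "progressor", welch = FALSE) {
  stopifnot(inherits(table, "analyte_table"))
  grp <- table$sample_meta$group
  if (!positive_group %in% grp)
    stop("group '", positive_group, "' absent from the table")
  pos <- grp == positive_group
  if (length(unique(grp[!pos])) != 1)
    stop("expected exactly two groups")
  x <- table$values
  res <- lapply(seq_len(ncol(x)), function(j) {
    tt <- two_sample_ttest(x[pos, j], x[!pos, j], welch = welch)
    c(fold_change(x[pos, j], x[!pos, j]), tt$statistic, tt$p_value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    analyte_id = colnames(x),
    fold_change = res[, 1],
    t = res[, 2],
    p_value = res[, 3],
    stringsAsFactors = FALSE
  )
  out$significant_05 <- out$p_value < 0.05
  out$significant_01 <- out$p_value < 0.01
  out$significant_bonferroni <- bonferroni(out$p_value, 0.05)
  out
}
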