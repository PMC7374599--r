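#' Hotelling's reduced-T2 score per sample
#'
#' Fits a PCA to the (autoscaled) data, retains the smallest number of
#' components `A` whose cumulative explained variance reaches `var_fraction`
#' (capped at `n - 2`), and scores each sample as
#' \deqn{T^2_i = \sum_{a=1}^{A} t_{ia}^2 / \lambda_a,}
#' where \eqn{t_{ia}} are PCA scores and \eqn{\lambda_a} the score variances.
#' The "reduced" score divides \eqn{T^2_i} by its 95% confidence limit
#' \deqn{T^2_{95} = \frac{A (n-1)(n+1)}{n (n-A)} F_{0.95}(A, n-A),}
#' so a reduced score of 1 sits exactly on the 95% limit and the
#' conventional pruning threshold of 5 means "five times the 95% limit".
#'
#' @param table autoscaled [analyte_table()] or numeric matrix.
#' @param var_fraction cumulative explained-variance fraction used to choose
#'   the component count (default 0.9).
#' @return Numeric vector of reduced-T2 scores, one per sample, with
#'   attribute `n_components` = A.
#' @export
reduced_t2 <- function(table, var_fraction = 0.9) {
  x <- if (inherits(table, "analyte_table")) table$values else table
  if (var_fraction <= 0 || var_fraction > 1)
    stop("`var_fraction` must be in (0, 1]")
  n <- nrow(x)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  pos <- lambda > .Machine$double.eps * lambda[1]
  lambda <- lambda[pos]
  cum <- cumsum(lambda) / sum(lambda)
  a <- which(cum >= var_fraction - 1e-12)[1]
  a <- min(a, n - 2L, length(lambda))
  if (n <= a + 1) stop("insufficient samples for ", a, " components")
  scores <- pc$x[, seq_len(a), drop = FALSE]
  t2 <- rowSums(sweep(scores^2, 2, lambda[seq_len(a)], "/"))
  t2_95 <- a * (n - 1) * (n + 1) / (n * (n - a)) * qf(0.95, a, n - a)
  out <- t2 / t2_95
  attr(out, "n_components") <- a
  out
}

#' Iteratively prune "negative driver" samples by reduced T2
#'
#' Samples that dominate a PCA model to the point that its components mainly
#' explain a single observation distort every downstream multivariate model.
#' This loop autoscales the data, computes [reduced_t2()] scores, removes the
#' single sample with the highest score above `threshold`, refits, and
#' repeats until all samples score below the threshold.
#'
#' @param table an [analyte_table()] with >= 10 samples (raw or scaled; the
#'   data are re-autoscaled at every iteration).
#' @param threshold reduced-T2 removal threshold (default 5).
#' @param var_fraction passed to [reduced_t2()].
#' @param max_remove_frac abort if the loop would remove more than this
#'   fraction of samples (default 0.5).
#' @return A list with elements `table` (the pruned table) and `report`, an
#'   `outlier_report` containing `removed_sample_ids` (in removal order),
#'   `t2_trace` (the removed sample's reduced score at each iteration) and
#'   `n_components_used`.
#' @export
prune_negative_drivers <- function(table, threshold = 5, var_fraction = 0.9,
                                   max_remove_frac = 0.5) {
  stopifnot(inherits(table, "analyte_table"))
  if (nrow(table$values) < 10) stop("need >= 10 samples to prune outliers")
  removed <- character()
  trace <- numeric()
  comps <- integer()
  n0 <- nrow(table$values)
  repeat {
    scaled <- autoscale(table, on_zero_variance = "drop")
    scores <- suppressWarnings(reduced_t2(scaled$table, var_fraction))
    worst <- which.max(scores)
    if (scores[worst] <= threshold) break
    removed <- c(removed, rownames(table$values)[worst])
    trace <- c(trace, scores[worst])
    comps <- c(comps, attr(scores, "n_components"))
    if (length(removed) > max_remove_frac * n0)
      stop("outlier pruning would remove more than ",
           round(100 * max_remove_frac), "% of samples; aborting")
    keep <- setdiff(seq_len(nrow(table$values)), worst)
    table <- subset_table(table, samples = keep)
  }
  report <- structure(
    list(removed_sample_ids = removed, t2_trace = trace,
         n_components_used = comps),
    class = "outlier_report"
  )
  list(table = table, report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  if (length(x$removed_sample_ids) == 0) {
    cat("outlier_report: no samples removed\n")
  } else {
    cat("outlier_report:", length(x$removed_sample_ids), "sample(s) removed\n")
    for (i in seq_along(x$removed_sample_ids)) {
      cat(sprintf("  %d. %s (reduced T2 = %.2f, A = %d)\n", i,
                  x$removed_sample_ids[i], x$t2_trace[i],
                  x$n_components_used[i]))
    }
  }
  invisible(x)
}
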