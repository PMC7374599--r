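# Pool per-time-point tables for one group into a single observation matrix
# with an ordinal time code (0, 1, 2, ... in time order).
.pool_time_points <- function(tables, group) {
  if (inherits(tables, "analyte_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, logical(1), "analyte_table")))
  weeks <- vapply(tables, function(t) unique(t$sample_meta$time_week)[1],
                  numeric(1))
  ord <- order(weeks)
  tables <- tables[ord]
  weeks <- weeks[ord]
  if (length(unique(weeks)) < 2)
    stop("need >= 2 distinct time points")
  common <- Reduce(intersect, lapply(tables, function(t) colnames(t$values)))
  if (length(common) == 0) stop("no shared analytes across time points")
  xs <- list(); time_code <- numeric(); week <- numeric()
  subject <- character()
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    rows <- which(tab$sample_meta$group == group)
    if (length(rows) == 0) stop("group '", group, "' absent at week ", weeks[i])
    x <- tab$values[rows, common, drop = FALSE]
    xs[[i]] <- x
    time_code <- c(time_code, rep(i - 1, length(rows)))
    week <- c(week, rep(weeks[i], length(rows)))
    subject <- c(subject, tab$sample_meta$subject_id[rows])
  }
  list(x = do.call(rbind, xs), time_code = time_code, week = week,
       subject = subject)
}

#' LASSO signature separating the collection time points within a group
#'
#' Pools all observations of one group across the time points, codes the
#' visits ordinally (0/1/2), autoscales the pooled matrix and runs
#' [lasso_cv()] with the time code as response. The result is the minimum
#' set of analytes whose expression tracks the visit sequence.
#'
#' @param tables list of per-time-point [analyte_table()]s (same group
#'   membership at each visit).
#' @param group group label (`"progressor"` / `"non_progressor"`).
#' @param k CV folds (default 10).
#' @param seed fold seed.
#' @param allow_empty passed to [lasso_cv()]; with `TRUE` an all-zero
#'   solution returns an empty signature (interpreted as "no temporal
#'   signal") instead of an error.
#' @return A `progsig_signature`.
#' @export
temporal_signature <- function(tables, group, k = 10, seed = 1,
                               allow_empty = FALSE) {
  pooled <- .pool_time_points(tables, group)
  sc <- autoscale(pooled$x, on_zero_variance = "drop")
  lasso_cv(sc$table, pooled$time_code, k = k, seed = seed,
           allow_empty = allow_empty)
}

#' Trajectory PCA of a temporal signature
#'
#' Restricts the pooled group observations to the signature analytes,
#' autoscales and fits a PCA. Each observation (subject x visit) receives
#' scores on the leading components; per-visit PC1 score lists and
#' per-subject score sequences are stored for the downstream ANOVA and
#' density summaries.
#'
#' @param tables list of per-time-point [analyte_table()]s.
#' @param signature `progsig_signature` or character vector of analyte IDs;
#'   every analyte must be present at every time point.
#' @param group group label.
#' @param n_pc number of components to keep (default 2).
#' @return A `trajectory_model`: `scores` (observations x PCs),
#'   `explained_variance` (all PCs), `per_time_pc1`, `time_week` and
#'   `subject` per observation, and the signature used.
#' @export
trajectory_pca <- function(tables, signature, group, n_pc = 2) {
  ids <- if (inherits(signature, "progsig_signature"))
    signature$analyte_ids else signature
  if (length(ids) == 0) stop("empty signature")
  pooled <- .pool_time_points(tables, group)
  missing_cols <- setdiff(ids, colnames(pooled$x))
  if (length(missing_cols))
    stop("signature analyte(s) missing from the tables: ",
         paste(missing_cols, collapse = ", "))
  x <- pooled$x[, ids, drop = FALSE]
  sc <- autoscale(x, on_zero_variance = "drop")$table
  pc <- prcomp(sc, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  structure(
    list(scores = scores, explained_variance = ev,
         loadings = pc$rotation[, seq_len(n_pc), drop = FALSE],
         per_time_pc1 = split(pc$x[, 1], pooled$week),
         time_week = pooled$week, subject = pooled$subject,
         group = group, signature = ids),
    class = "trajectory_model"
  )
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("trajectory_model (%s): %d observations, %d signature analytes\n",
              x$group, nrow(x$scores), length(x$signature)))
  cat(sprintf("  PC1+PC2 explained variance: %.2f%%\n",
              100 * sum(x$explained_variance[seq_len(min(2, length(x$explained_variance)))])))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD on PC1 scores across time points
#'
#' Tests whether the per-visit PC1 score distributions differ, treating
#' observations as independent (within-subject correlation across visits is
#' deliberately ignored, matching the conventional fold of this analysis;
#' a repeated-measures model is out of scope).
#'
#' @param model a `trajectory_model`.
#' @return List with `anova_f`, `anova_p`, `df` and `tukey` (pairwise
#'   data.frame with adjusted p-values). Time points with fewer than 2
#'   observations are excluded with a warning.
#' @export
pc1_anova <- function(model) {
  stopifnot(inherits(model, "trajectory_model"))
  groups <- model$per_time_pc1
  small <- lengths(groups) < 2
  if (any(small)) {
    warning("excluding time point(s) with < 2 observations: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2) stop("need >= 2 time points with >= 2 observations")
  res <- .oneway_tukey(groups)
  list(anova_f = res$anova_f, anova_p = res$anova_p, df = res$df,
       tukey = res$tukey, degenerate = res$degenerate)
}

#' Gaussian kernel density of PC1 scores per time point
#'
#' One density per visit, Gaussian kernel with the normal-reference
#' bandwidth \eqn{h = \hat\sigma (4 / (3n))^{1/5}}, evaluated on a shared
#' grid spanning all scores plus three bandwidths on either side.
#'
#' @param model a `trajectory_model`.
#' @param n_grid grid resolution (default 512).
#' @return Named list (one element per time point) of lists with `grid`,
#'   `density`, `bandwidth`, `n`; a zero-variance score list yields a
#'   `degenerate = TRUE` entry instead of a density.
#' @export
kde_pc1 <- function(model, n_grid = 512) {
  stopifnot(inherits(model, "trajectory_model"))
  groups <- model$per_time_pc1
  if (any(lengths(groups) < 2)) stop("need >= 2 scores per time point")
  bw <- vapply(groups, function(x) sd(x) * (4 / (3 * length(x)))^(1 / 5),
               numeric(1))
  all_scores <- unlist(groups)
  pad <- 3 * max(bw, na.rm = TRUE)
  lo <- min(all_scores) - pad
  hi <- max(all_scores) + pad
  lapply(setNames(names(groups), names(groups)), function(tw) {
    x <- groups[[tw]]
    h <- bw[[tw]]
    if (!is.finite(h) || h <= 0)
      return(list(degenerate = TRUE, n = length(x)))
    d <- density(x, bw = h, kernel = "gaussian", from = lo, to = hi,
                 n = n_grid)
    list(grid = d$x, density = d$y, bandwidth = h, n = length(x),
         degenerate = FALSE)
  })
}
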