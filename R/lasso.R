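#' Fit the LASSO at a fixed penalty by cyclic coordinate descent
#'
#' Minimises \deqn{\frac{1}{2n}\|y - X\beta\|_2^2 + \lambda\|\beta\|_1} by
#' cyclic coordinate descent with soft-thresholding (compiled inner loop).
#' No intercept is fitted: predictors are expected autoscaled and the
#' response is centred internally. Convergence is declared when the largest
#' coefficient change in a full cycle falls below `tol`.
#'
#' @param X numeric predictor matrix (autoscaled).
#' @param y numeric response (class coding 0/1 or ordinal time 0/1/2; it is
#'   centred before fitting).
#' @param lambda penalty, a single value >= 0 or a decreasing sequence
#'   (solved with warm starts).
#' @param tol convergence tolerance on the max coefficient change per
#'   cycle (default 1e-9, which keeps the solution within ~1e-6 of the
#'   exact minimiser even on strongly correlated designs).
#' @param maxit maximum coordinate-descent cycles per lambda.
#' @return For a single lambda, a named coefficient vector; for a sequence,
#'   a p x length(lambda) coefficient matrix.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-9, maxit = 100000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite entries in X or y")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(lambda < 0)) stop("`lambda` must be >= 0")
  if (is.unsorted(rev(lambda))) lambda <- sort(lambda, decreasing = TRUE)
  yc <- y - mean(y)
  beta <- .cd_lasso_path(X, yc, as.numeric(lambda), tol, as.integer(maxit))
  rownames(beta) <- colnames(X)
  if (length(lambda) == 1) beta[, 1] else beta
}

# Smallest penalty at which all coefficients are exactly zero.
.lambda_max <- function(X, y) {
  yc <- y - mean(y)
  max(abs(crossprod(X, yc))) / nrow(X)
}

# Geometric penalty grid from lambda_max down to ratio * lambda_max.
.lambda_grid <- function(X, y, nlambda = 100, ratio = 1e-3) {
  lmax <- .lambda_max(X, y)
  if (lmax <= 0) lmax <- .Machine$double.eps
  exp(seq(log(lmax), log(ratio * lmax), length.out = nlambda))
}

# Seeded fold assignment stratified by the distinct values of y (so no
# training fold loses a class/time level entirely); continuous responses
# (many distinct values) fall back to plain randomisation.
.stratified_folds <- function(y, k, seed) {
  .with_seed(seed, {
    n <- length(y)
    strata <- if (length(unique(y)) <= max(10, k)) y else rep(1, n)
    fold <- integer(n)
    for (lev in unique(strata)) {
      idx <- which(strata == lev)
      start <- sample.int(k, 1)  # rotate so small strata spread evenly
      f <- (start + seq_along(idx) - 2L) %% k + 1L
      fold[idx] <- f[sample.int(length(idx))]
    }
    fold
  })
}

#' LASSO signature selection with k-fold cross-validation
#'
#' Builds a 100-point geometric penalty grid from \eqn{\lambda_{max}} (the
#' smallest penalty with an all-zero solution) down to
#' \eqn{10^{-3}\lambda_{max}}, estimates the mean squared prediction error
#' of each penalty by seeded, stratified k-fold cross-validation, refits on
#' the full data at the error-minimising penalty, and returns the nonzero
#' coefficients as a signature. Ties in the CV error are broken toward the
#' larger (sparser) penalty.
#'
#' @param X autoscaled predictor matrix (columns named by analyte).
#' @param y numeric response: class coding 0/1 or ordinal time coding 0/1/2.
#' @param k number of folds (default 10; `k = n` gives leave-one-out).
#' @param seed integer seed controlling the fold assignment.
#' @param nlambda,lambda_min_ratio penalty grid size and extent.
#' @param compartments optional named vector tagging each analyte with its
#'   tissue compartment (copied into the signature).
#' @param allow_empty if `TRUE`, an all-zero solution at the selected
#'   penalty returns a zero-analyte signature instead of an error.
#' @param cv_tol coordinate-descent tolerance for the fold paths (the CV
#'   error surface does not need full precision); the final refit at the
#'   selected penalty always uses the default [lasso_fit()] tolerance.
#' @return A `progsig_signature` with analytes ordered by |coefficient|
#'   (descending), the selected penalty, the CV error curve and the fold
#'   assignment.
#' @export
lasso_cv <- function(X, y, k = 10, seed = 1, nlambda = 100,
                     lambda_min_ratio = 1e-3, compartments = NULL,
                     allow_empty = FALSE, cv_tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("need n >= k for ", k, "-fold cross-validation")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  lambda <- .lambda_grid(X, y, nlambda, lambda_min_ratio)
  fold <- .stratified_folds(y, k, seed)
  sq_err <- matrix(NA_real_, n, length(lambda))
  for (f in seq_len(k)) {
    test <- fold == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    beta <- lasso_fit(Xtr, ytr, lambda, tol = cv_tol)
    pred <- X[test, , drop = FALSE] %*% beta + mean(ytr)
    sq_err[test, ] <- (pred - y[test])^2
  }
  cvm <- colMeans(sq_err)
  best <- which(cvm <= min(cvm) + 1e-12)[1]  # ties -> larger penalty
  beta_full <- lasso_fit(X, y, lambda[seq_len(best)])
  coef_best <- if (best == 1) beta_full else beta_full[, best]
  nz <- which(coef_best != 0)
  if (length(nz) == 0 && !allow_empty)
    stop("empty signature: the CV-selected penalty (lambda = ",
         signif(lambda[best], 4), ", index ", best,
         " of ", length(lambda), ") zeroed every coefficient")
  ord <- nz[order(abs(coef_best[nz]), decreasing = TRUE)]
  new_signature(
    analyte_ids = colnames(X)[ord],
    weights = coef_best[ord],
    method = "lasso_cv",
    lambda_selected = lambda[best],
    compartments = compartments,
    extra = list(lambda_grid = lambda, cv_mse = cvm,
                 fold_assignment = fold, seed = seed)
  )
}

# Shared constructor for selection results.
new_signature <- function(analyte_ids, weights, method,
                          lambda_selected = NA_real_, compartments = NULL,
                          extra = list()) {
  comp <- if (!is.null(compartments)) {
    unname(compartments[analyte_ids])
  } else {
    rep(NA_character_, length(analyte_ids))
  }
  structure(
    c(list(analyte_ids = analyte_ids,
           weights = setNames(unname(weights), analyte_ids),
           method = method, lambda_selected = lambda_selected,
           compartments = setNames(comp, analyte_ids)),
      extra),
    class = "progsig_signature"
  )
}

#' @export
print.progsig_signature <- function(x, ...) {
  cat(sprintf("progsig_signature (%s): %d analyte(s)\n", x$method,
              length(x$analyte_ids)))
  if (!is.na(x$lambda_selected))
    cat(sprintf("  lambda = %.4g\n", x$lambda_selected))
  show <- utils::head(x$analyte_ids, 10)
  cat("  top:", paste(sprintf("%s (%.3g)", show, x$weights[show]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.progsig_signature <- function(x) length(x$analyte_ids)

#' Select a signature by VIP-score threshold
#'
#' Keeps every analyte whose variable-importance-in-projection score in a
#' fitted PLS-DA model reaches the cutoff (conventionally 1, the mean-square
#' VIP), ordered by VIP descending.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param cutoff inclusion threshold (default 1).
#' @return A `progsig_signature` with VIP scores as weights.
#' @export
vip_select <- function(model, cutoff = 1) {
  stopifnot(inherits(model, "pls_model"))
  vip <- vip_scores(model)
  keep <- which(vip >= cutoff)
  if (length(keep) == 0)
    stop("empty signature: no analyte reaches VIP >= ", cutoff)
  ord <- keep[order(vip[keep], decreasing = TRUE)]
  new_signature(names(vip)[ord], vip[ord], method = "vip")
}
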