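#' Fit a PLS discriminant analysis model (NIPALS PLS1)
#'
#' Codes the two classes numerically (first factor level 0, second 1),
#' centres the coding and runs NIPALS PLS1 with X-deflation per latent
#' variable (LV): weights \eqn{w_a \propto X_a'y_a} (unit norm), scores
#' \eqn{t_a = X_a w_a}, X-loadings \eqn{p_a = X_a't_a / t_a't_a}, Y-loading
#' \eqn{q_a = y_a't_a / t_a't_a}, then \eqn{X_{a+1} = X_a - t_a p_a'} and
#' \eqn{y_{a+1} = y_a - q_a t_a}. Per-LV explained X-variance and the
#' Y-variance captured by each LV (used for VIP scores) are stored.
#'
#' @param X autoscaled numeric matrix (samples x analytes) or an
#'   [analyte_table()] that is already autoscaled.
#' @param classes factor/character vector of two class labels, or a numeric
#'   response (used as-is after centring).
#' @param n_lv number of latent variables (default 2; must not exceed
#'   `min(n - 1, p)` or the rank of X).
#' @param scaling optional `scaling_params` used to scale prediction data.
#' @return A `pls_model` with weights `W`, X-loadings `P`, scores `Tmat`,
#'   Y-loadings `q`, regression vector `b`, class coding, per-LV explained
#'   X-variance and Y sum-of-squares, and VIP scores.
#' @export
fit_plsda <- function(X, classes, n_lv = 2, scaling = NULL) {
  if (inherits(X, "analyte_table")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.numeric(classes)) {
    class_codes <- NULL
    y <- classes
    labels <- NULL
  } else {
    labels <- factor(classes)
    if (nlevels(labels) != 2)
      stop("PLS-DA requires exactly two classes; got ", nlevels(labels))
    class_codes <- setNames(c(0, 1), levels(labels))
    y <- class_codes[as.character(labels)]
  }
  if (n_lv > min(n - 1, p))
    stop("n_lv = ", n_lv, " exceeds min(n - 1, p) = ", min(n - 1, p))
  ybar <- mean(y)
  yc <- y - ybar
  Xa <- X
  ya <- yc
  W <- P <- matrix(0, p, n_lv, dimnames = list(colnames(X), NULL))
  Tmat <- matrix(0, n, n_lv, dimnames = list(rownames(X), NULL))
  q <- numeric(n_lv)
  ssx_total <- sum(Xa^2)
  explained_x <- numeric(n_lv)
  ssy <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("n_lv = ", n_lv, " exceeds the predictive rank of X (LV ", a, ")")
    w <- w / nw
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12)
      stop("degenerate score vector at LV ", a)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - t_a %*% t(p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tmat[, a] <- t_a
    q[a] <- q_a
    explained_x[a] <- tt * sum(p_a^2) / ssx_total
    ssy[a] <- q_a^2 * tt
  }
  b <- W %*% solve(crossprod(P, W), q)
  model <- structure(
    list(n_lv = n_lv, W = W, P = P, Tmat = Tmat, q = q, b = drop(b),
         y_mean = ybar, class_codes = class_codes, labels = labels,
         orthogonalized = FALSE, explained_x_variance = explained_x,
         ssy = ssy, scaling = scaling,
         analyte_ids = colnames(X)),
    class = "pls_model"
  )
  model$vip <- vip_scores(model)
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d LV(s), %d analytes%s\n", x$n_lv,
              length(x$analyte_ids),
              if (x$orthogonalized) " (orthogonalized)" else ""))
  cat(sprintf("  explained X-variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_x_variance),
                    collapse = ", ")))
  if (!is.null(x$class_codes))
    cat("  classes:", paste(sprintf("%s=%d", names(x$class_codes),
                                    x$class_codes), collapse = ", "), "\n")
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' \deqn{VIP_j = \sqrt{p \cdot \frac{\sum_a SSY_a w_{ja}^2}{\sum_a SSY_a}}}
#' with unit-norm weight vectors and \eqn{SSY_a} the Y sum of squares
#' explained by LV a. The mean square of the VIP scores is exactly 1
#' (\eqn{\sum_j VIP_j^2 = p}).
#'
#' @param model a fitted `pls_model`.
#' @return Named numeric vector of per-analyte VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$ssy
  if (sum(ssy) <= 0) stop("degenerate model: no Y variance explained")
  p <- nrow(model$W)
  vip2 <- p * as.vector(model$W^2 %*% ssy) / sum(ssy)
  setNames(sqrt(vip2), rownames(model$W))
}

#' Orthogonalize a fitted PLS-DA model
#'
#' Post-hoc rotation of the score space in the style of orthogonal PLS:
#' the rotated LV1 score is proportional to the fitted response, so all
#' class-predictive variation concentrates on LV1 while the remaining
#' components carry only Y-uncorrelated variation. Fitted values and class
#' predictions are unchanged (the rotation spans the same score space).
#' LV1 is sign-oriented so the class coded 0 (the first factor level, e.g.
#' non-progressors) has a positive mean score.
#'
#' @param model a fitted `pls_model` with `n_lv >= 2` (an `n_lv = 1` model
#'   is returned unchanged with a warning).
#' @return The rotated `pls_model` (`orthogonalized = TRUE`); rotated
#'   scores have unit-norm columns, with the matching scale carried in the
#'   loadings.
#' @export
orthogonalize <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$n_lv < 2) {
    warning("n_lv = 1: orthogonalization is the identity")
    return(model)
  }
  Tm <- model$Tmat
  snorm <- sqrt(colSums(Tm^2))
  U <- sweep(Tm, 2, snorm, "/")           # orthonormal score basis
  S <- diag(snorm, model$n_lv)
  target <- S %*% model$q                 # fitted y in U-coordinates
  if (sqrt(sum(target^2)) < 1e-12)
    stop("degenerate model: zero fitted response")
  r1 <- target / sqrt(sum(target^2))
  R <- qr.Q(qr(cbind(r1, diag(model$n_lv))))[, seq_len(model$n_lv)]
  # qr may flip the first column's sign; force column 1 = r1
  if (sum(R[, 1] * r1) < 0) R[, 1] <- -R[, 1]
  R[, 1] <- r1
  Tstar <- U %*% R
  Pstar <- model$P %*% S %*% R
  qstar <- drop(crossprod(R, S %*% model$q))
  Wstar <- model$W %*% S %*% R            # same rotation, for reference
  # orient LV1: class coded 0 scores positive
  if (!is.null(model$class_codes)) {
    y01 <- model$class_codes[as.character(model$labels)]
    if (mean(Tstar[y01 == 0, 1]) < 0) {
      Tstar[, 1] <- -Tstar[, 1]
      Pstar[, 1] <- -Pstar[, 1]
      Wstar[, 1] <- -Wstar[, 1]
      qstar[1] <- -qstar[1]
    }
  }
  ssx_per_lv <- colSums(Pstar^2)          # scores are unit norm
  model$Tmat <- Tstar
  model$P <- Pstar
  model$W_rotated <- Wstar
  model$q_rotated <- qstar
  model$explained_x_variance <- ssx_per_lv / sum(ssx_per_lv) *
    sum(model$explained_x_variance)
  model$orthogonalized <- TRUE
  model
}

#' Predict classes and continuous scores from a PLS-DA model
#'
#' The continuous score is the PLS regression prediction of the class
#' coding; the class is the code nearest the score, i.e. a midpoint
#' threshold of 0.5 for 0/1 coding, with scores exactly at the midpoint
#' assigned to the higher-coded class.
#'
#' @param object a `pls_model`.
#' @param newdata matrix or [analyte_table()]; scaled with the model's
#'   `scaling_params` when the model carries them, otherwise assumed
#'   already scaled.
#' @param ... unused.
#' @return List with `score` (continuous) and `class` (labels when the
#'   model was fitted on labels, otherwise the numeric code).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "analyte_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) &&
      ncol(newdata) == length(object$analyte_ids))
    colnames(newdata) <- object$analyte_ids
  if (!is.null(object$scaling)) newdata <- apply_scaling(newdata, object$scaling)
  missing_cols <- setdiff(object$analyte_ids, colnames(newdata))
  if (length(missing_cols))
    stop("newdata lacks analyte(s): ", paste(missing_cols, collapse = ", "))
  newdata <- newdata[, object$analyte_ids, drop = FALSE]
  score <- drop(newdata %*% object$b) + object$y_mean
  if (is.null(object$class_codes))
    return(list(score = score, class = score))
  codes <- sort(object$class_codes)
  midpoint <- mean(codes)
  cls <- ifelse(score >= midpoint, names(codes)[2], names(codes)[1])
  list(score = score, class = cls)
}

#' Cross-validated PLS-DA accuracy
#'
#' Seeded, stratified k-fold cross-validation in which everything --
#' autoscaling, the LV-count choice and the PLS fit -- is recomputed inside
#' each training fold: the training fold is autoscaled (zero-variance
#' analytes dropped), an inner stratified CV over the training samples
#' picks the LV count with the lowest inner misclassification error (ties
#' toward fewer LVs), and held-out samples are scaled with the training
#' fold's parameters before prediction.
#'
#' @param X raw (unscaled) matrix or [analyte_table()].
#' @param classes two-level class labels.
#' @param k outer folds (default 10).
#' @param seed controls both fold assignments.
#' @param n_lv_max largest LV count considered (default 10, capped by fold
#'   size and rank).
#' @param inner_k folds of the inner LV-selection CV (default 5).
#' @return A `cv_result` with `per_fold_accuracy`, `pooled_cv_accuracy`,
#'   `per_sample_prediction`, `per_sample_score`, `fold_assignment` and
#'   `n_lv_chosen`.
#' @export
cross_validate <- function(X, classes, k = 10, seed = 1, n_lv_max = 10,
                           inner_k = 5) {
  if (inherits(X, "analyte_table")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("need n >= k")
  labels <- factor(classes)
  if (nlevels(labels) != 2) stop("two classes required")
  fold <- .stratified_folds(as.character(labels), k, seed)
  if (any(tapply(fold, labels, function(f) length(unique(f))) < 1))
    stop("stratification failed: a class is absent from a training fold")
  pred <- character(n)
  score <- numeric(n)
  lv_used <- integer(k)
  for (f in seq_len(k)) {
    test <- fold == f
    if (nlevels(droplevels(labels[!test])) < 2)
      stop("class absent from training fold ", f)
    sc <- autoscale(X[!test, , drop = FALSE], on_zero_variance = "drop")
    Xtr <- sc$table
    ytr <- labels[!test]
    lv_max_f <- min(n_lv_max, nrow(Xtr) - 2, ncol(Xtr))
    n_lv <- .choose_n_lv(Xtr, ytr, lv_max_f, inner_k,
                         seed = seed + 1000L + f)
    fit <- fit_plsda(Xtr, ytr, n_lv = n_lv)
    Xte <- apply_scaling(X[test, , drop = FALSE], sc$params)
    pr <- predict(fit, Xte)
    pred[test] <- pr$class
    score[test] <- pr$score
    lv_used[f] <- n_lv
  }
  correct <- pred == as.character(labels)
  per_fold <- tapply(correct, fold, mean)
  structure(
    list(per_fold_accuracy = as.numeric(per_fold),
         pooled_cv_accuracy = mean(correct),
         per_sample_prediction = setNames(pred, rownames(X)),
         per_sample_score = setNames(score, rownames(X)),
         per_sample_correct = setNames(correct, rownames(X)),
         fold_assignment = fold, n_lv_chosen = lv_used),
    class = "cv_result"
  )
}

# Inner CV over LV counts; returns the count with the lowest inner
# misclassification error (ties -> fewer LVs).
.choose_n_lv <- function(X, labels, lv_max, inner_k, seed) {
  lv_max <- max(1L, lv_max)
  if (lv_max == 1L) return(1L)
  inner_k <- min(inner_k, nrow(X))
  fold <- .stratified_folds(as.character(labels), inner_k, seed)
  err <- matrix(NA_real_, inner_k, lv_max)
  for (f in seq_len(inner_k)) {
    test <- fold == f
    if (nlevels(droplevels(labels[!test])) < 2) next
    sc <- autoscale(X[!test, , drop = FALSE], on_zero_variance = "drop")
    lv_cap <- min(lv_max, nrow(sc$table) - 1, ncol(sc$table))
    Xte <- apply_scaling(X[test, , drop = FALSE], sc$params)
    for (a in seq_len(lv_cap)) {
      fit <- try(fit_plsda(sc$table, labels[!test], n_lv = a), silent = TRUE)
      if (inherits(fit, "try-error")) break
      err[f, a] <- mean(predict(fit, Xte)$class != as.character(labels[test]))
    }
  }
  mean_err <- colMeans(err, na.rm = TRUE)
  mean_err[is.nan(mean_err)] <- Inf
  which.min(mean_err)  # first minimum = fewest LVs
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: pooled accuracy %.1f%% over %d folds (sizes %s)\n",
              100 * x$pooled_cv_accuracy, length(x$per_fold_accuracy),
              paste(range(table(x$fold_assignment)), collapse = "-")))
  invisible(x)
}

#' Confusion-matrix classification metrics
#'
#' @param predicted,truth class label vectors of equal length.
#' @param positive_class label counted as "positive" for
#'   sensitivity/PPV.
#' @return A `classification_metrics` list: confusion counts `tp`, `fn`,
#'   `tn`, `fp` and proportions `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`. A metric whose denominator is empty (class absent) is
#'   `NA` and listed in `undefined`.
#' @export
classification_metrics <- function(predicted, truth, positive_class) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  pos <- truth == positive_class
  ppos <- predicted == positive_class
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  out <- list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = (tp + tn) / length(truth),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn)
  )
  out$undefined <- names(out)[vapply(out, function(v)
    length(v) == 1 && is.na(v), logical(1))]
  structure(out, class = "classification_metrics")
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique continuous scores (higher
#' score = more likely positive) and integrates the area under the curve by
#' the trapezoidal rule.
#'
#' @param scores continuous classifier scores.
#' @param truth class labels.
#' @param positive_class label whose higher scores count as positive.
#' @return A `roc_curve` list: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(scores, truth, positive_class) {
  pos <- truth == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}
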