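# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package (KKT enumeration instead of
# coordinate descent; explicit eigen-decompositions instead of NIPALS).

# Exact LASSO solution of (1/2n)||yc - X b||^2 + lambda ||b||_1 by
# enumerating all sign patterns and checking the KKT conditions. Feasible
# for p <= 8 or so.
lasso_enumeration_oracle <- function(X, y, lambda, tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  yc <- y - mean(y)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (i in seq_len(nrow(patterns))) {
    s <- patterns[i, ]
    active <- which(s != 0)
    b <- numeric(p)
    if (length(active)) {
      XA <- X[, active, drop = FALSE]
      rhs <- crossprod(XA, yc) / n - lambda * s[active]
      sol <- try(solve(crossprod(XA) / n, rhs), silent = TRUE)
      if (inherits(sol, "try-error")) next
      if (any(sign(sol) != s[active])) next
      b[active] <- sol
    }
    grad <- abs(crossprod(X, yc - X %*% b)) / n
    inactive <- setdiff(seq_len(p), active)
    if (all(grad[inactive] <= lambda + tol)) return(b)
  }
  stop("oracle found no KKT point")
}

# PLS1 reference built from eigen-decompositions: each weight vector is the
# dominant eigenvector of X_a' y_a y_a' X_a (computed via eigen(), not the
# NIPALS power step), with the same deflation scheme.
pls_eigen_oracle <- function(X, y, n_lv) {
  X <- as.matrix(X)
  yc <- y - mean(y)
  Xa <- X; ya <- yc
  p <- ncol(X); n <- nrow(X)
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    M <- crossprod(Xa, ya) %*% crossprod(ya, Xa)  # = X'y y'X
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - t_a %*% t(p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  b <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, Tmat = Tm, q = q, b = drop(b), y_mean = mean(y))
}

# Agreement up to a per-column sign flip.
expect_equal_up_to_sign <- function(a, b, tol) {
  a <- as.matrix(a); b <- as.matrix(b)
  expect_equal(dim(a), dim(b))
  for (j in seq_len(ncol(a))) {
    d <- min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
    expect_lt(d, tol)
  }
}

# Adjusted Rand index between two labelings (contingency-table closed form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
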