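#include <Rcpp.h>
using namespace Rcpp;

inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the penalised least-squares objective
//   (1/2n) * ||y - X b||^2 + lambda * ||b||_1
// solved along a decreasing lambda sequence with warm starts.
// X is used as given (no internal standardisation); callers are expected
// to pass autoscaled predictors and a centred response.
// Returns a p x nlambda matrix of coefficients.
// [[Rcpp::export(name = ".cd_lasso_path")]]
NumericMatrix cd_lasso_path(const NumericMatrix& X, const NumericVector& y,
                            const NumericVector& lambda,
                            double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  NumericMatrix beta(p, nl);
  std::vector<double> b(p, 0.0), r(y.begin(), y.end());
  std::vector<double> xss(p);  // (1/n) * sum x_j^2
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xss[j] = s / n;
  }
  std::vector<char> active(p, 0);
  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    int iter_budget = maxit;
    // alternate full KKT-checking sweeps with cheap active-set sweeps
    // (the strategy used by coordinate-descent LASSO solvers generally)
    while (iter_budget > 0) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {           // full sweep
        if (xss[j] <= 0.0) { b[j] = 0.0; continue; }
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += X(i, j) * r[i];
        const double z = xr / n + xss[j] * b[j];
        const double bj = soft_threshold(z, lam) / xss[j];
        const double d = bj - b[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= d * X(i, j);
          b[j] = bj;
          const double ad = std::abs(d);
          if (ad > max_delta) max_delta = ad;
        }
        active[j] = (b[j] != 0.0);
      }
      --iter_budget;
      if (max_delta < tol) break;             // full sweep converged: done
      while (iter_budget > 0) {               // inner active-set sweeps
        double inner_delta = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!active[j] || xss[j] <= 0.0) continue;
          double xr = 0.0;
          for (int i = 0; i < n; ++i) xr += X(i, j) * r[i];
          const double z = xr / n + xss[j] * b[j];
          const double bj = soft_threshold(z, lam) / xss[j];
          const double d = bj - b[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= d * X(i, j);
            b[j] = bj;
            const double ad = std::abs(d);
            if (ad > inner_delta) inner_delta = ad;
          }
        }
        --iter_budget;
        if (inner_delta < tol) break;         // then re-check with full sweep
      }
    }
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return beta;
}
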