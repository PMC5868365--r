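#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the penalized least-squares objective
//
//   ||y - X b||_2^2 + l1 * ||b||_1 + l2 * ||b||_2^2
//
// on the literal residual-sum-of-squares scale (no 1/N factor), with the
// intercept handled outside (X columns centered, y centered). The coordinate
// update is the soft threshold
//
//   b_j <- S(x_j' r + ||x_j||^2 b_j, l1/2) / (||x_j||^2 + l2)
//
// so the subgradient condition for the all-zero solution is
// max_j |2 x_j' y| <= l1.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static int cd_solve(const NumericMatrix& X, const std::vector<double>& xtx,
                    std::vector<double>& r, std::vector<double>& beta,
                    double l1, double l2, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol();
  const double half_l1 = 0.5 * l1;
  for (int it = 1; it <= maxit; ++it) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
      const double* xj = &X(0, j);
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
      rho += xtx[j] * beta[j];
      double bnew = soft(rho, half_l1) / (xtx[j] + l2);
      double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
        beta[j] = bnew;
        double ad = std::fabs(d);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) return it;
  }
  return -maxit;  // negative signals non-convergence
}

// [[Rcpp::export(name = ".enet_cd")]]
List enet_cd(NumericMatrix X, NumericVector y, double l1, double l2,
             NumericVector beta0, double tol = 1e-8, int maxit = 1000000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> xtx(p), r(n);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int j = 0; j < p; ++j) fit += X(i, j) * beta[j];
    r[i] = y[i] - fit;
  }
  int it = cd_solve(X, xtx, r, beta, l1, l2, tol, maxit);
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["iters"] = std::abs(it),
                      _["converged"] = it > 0);
}

// Warm-started solution path over a penalty-magnitude grid. Column m of the
// result minimizes ||y - X b||^2 + l1s[m] ||b||_1 + l2s[m] ||b||_2^2.
// Magnitudes should be ordered large-to-small so warm starts track the path.
// [[Rcpp::export(name = ".enet_path")]]
NumericMatrix enet_path(NumericMatrix X, NumericVector y, NumericVector l1s,
                        NumericVector l2s, double tol = 1e-8,
                        int maxit = 1000000) {
  const int n = X.nrow(), p = X.ncol(), m = l1s.size();
  NumericMatrix out(p, m);
  std::vector<double> beta(p, 0.0), xtx(p), r(y.begin(), y.end());
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int k = 0; k < m; ++k) {
    int it = cd_solve(X, xtx, r, beta, l1s[k], l2s[k], tol, maxit);
    if (it < 0) stop("coordinate descent failed to converge in %d iterations",
                     maxit);
    for (int j = 0; j < p; ++j) out(j, k) = beta[j];
  }
  return out;
}
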