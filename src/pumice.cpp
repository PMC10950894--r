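#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the differential elastic-net objective
//
//   L(b) = ||y - X b||^2 + (1/2)(lambda/2) * sum_j pf_j b_j^2
//                        + (1/2) lambda   * sum_j pf_j |b_j|
//
// with pf_j = phi for "essential" predictors and 1 otherwise (phi <= 1, so
// annotated predictors are never penalised more).  Columns of X are assumed
// centred; y centred.  The coordinate update is the exact univariate
// minimiser:  b_j = S(x_j' r_j, lambda*pf_j/4) / (x_j'x_j + lambda*pf_j/4).

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

static double objective(const NumericMatrix& X, const NumericVector& y,
                        const NumericVector& b, const NumericVector& pf,
                        double lambda) {
  const int n = X.nrow(), p = X.ncol();
  double rss = 0.0;
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int j = 0; j < p; ++j) fit += X(i, j) * b[j];
    double e = y[i] - fit;
    rss += e * e;
  }
  double l2 = 0.0, l1 = 0.0;
  for (int j = 0; j < p; ++j) {
    l2 += pf[j] * b[j] * b[j];
    l1 += pf[j] * std::fabs(b[j]);
  }
  return rss + 0.25 * lambda * l2 + 0.5 * lambda * l1;
}

// [[Rcpp::export(name = ".pumice_cd")]]
List pumice_cd(NumericMatrix X, NumericVector y, NumericVector pf,
               double lambda, NumericVector b_init,
               double tol = 1e-9, int max_iter = 10000,
               bool check_objective = false) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector b = clone(b_init);
  NumericVector xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  // residual r = y - X b
  NumericVector r(n);
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int j = 0; j < p; ++j) if (b[j] != 0.0) fit += X(i, j) * b[j];
    r[i] = y[i] - fit;
  }
  double obj_prev = R_PosInf;
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { b[j] = 0.0; continue; }
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
      rho += xtx[j] * b[j];                      // x_j' (r + x_j b_j)
      double pen = 0.25 * lambda * pf[j];
      double bj_new = soft(rho, pen) / (xtx[j] + pen);
      double d = bj_new - b[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        b[j] = bj_new;
        double scaled = std::fabs(d) * std::sqrt(xtx[j] / n);
        if (scaled > max_delta) max_delta = scaled;
      }
    }
    if (check_objective) {
      double obj = objective(X, y, b, pf, lambda);
      if (obj > obj_prev + 1e-8 * (1.0 + std::fabs(obj_prev)))
        stop("coordinate-descent objective increased between sweeps");
      obj_prev = obj;
    }
    if (max_delta < tol) { converged = true; ++iter; break; }
  }
  return List::create(_["beta"] = b,
                      _["converged"] = converged,
                      _["iterations"] = iter,
                      _["objective"] = objective(X, y, b, pf, lambda));
}

// Pathwise solver with warm starts: lambdas must be sorted decreasing.
// Returns p x L coefficient matrix.
// [[Rcpp::export(name = ".pumice_cd_path")]]
NumericMatrix pumice_cd_path(NumericMatrix X, NumericVector y, NumericVector pf,
                             NumericVector lambdas,
                             double tol = 1e-9, int max_iter = 10000) {
  const int p = X.ncol(), L = lambdas.size();
  NumericMatrix out(p, L);
  NumericVector b(p);  // zeros
  for (int l = 0; l < L; ++l) {
    List fit = pumice_cd(X, y, pf, lambdas[l], b, tol, max_iter, false);
    NumericVector bl = fit["beta"];
    b = clone(bl);
    for (int j = 0; j < p; ++j) out(j, l) = bl[j];
  }
  return out;
}
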