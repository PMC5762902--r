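#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Banded LDL^T solve for a symmetric positive-definite pentadiagonal system.
// Diagonals: d0 (main, length n), d1 (first off, n-1), d2 (second off, n-2).
// b is overwritten with the solution.
static void penta_solve(const std::vector<double>& d0,
                        const std::vector<double>& d1,
                        const std::vector<double>& d2,
                        std::vector<double>& b,
                        std::vector<double>& dd,
                        std::vector<double>& l1,
                        std::vector<double>& l2) {
  const int n = (int)d0.size();
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= l1[i - 1] * l1[i - 1] * dd[i - 1];
    if (i >= 2) di -= l2[i - 2] * l2[i - 2] * dd[i - 2];
    dd[i] = di;
    if (i + 1 < n) {
      double e = d1[i];
      if (i >= 1) e -= l1[i - 1] * l2[i - 1] * dd[i - 1];
      l1[i] = e / dd[i];
    }
    if (i + 2 < n) l2[i] = d2[i] / dd[i];
  }
  for (int i = 0; i < n; ++i) {
    double v = b[i];
    if (i >= 1) v -= l1[i - 1] * b[i - 1];
    if (i >= 2) v -= l2[i - 2] * b[i - 2];
    b[i] = v;
  }
  for (int i = 0; i < n; ++i) b[i] /= dd[i];
  for (int i = n - 1; i >= 0; --i) {
    double v = b[i];
    if (i + 1 < n) v -= l1[i] * b[i + 1];
    if (i + 2 < n) v -= l2[i] * b[i + 2];
    b[i] = v;
  }
}

// Asymmetric least squares baselines for the rows of Y.
// Minimizes sum_i w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2 with
// w_i = p where y_i > z_i else 1 - p, iterated to weight convergence.
// [[Rcpp::export(name = ".asls_baselines")]]
NumericMatrix asls_baselines(NumericMatrix Y, double lambda, double p,
                             int max_iter) {
  const int nr = Y.nrow(), n = Y.ncol();
  NumericMatrix Z(nr, n);
  if (n < 4) stop("spectrum too short for AsLS");

  // lambda * D2' D2 diagonals (D2 = second-difference operator)
  std::vector<double> p0(n), p1(n - 1), p2(n - 2);
  for (int i = 0; i < n; ++i) {
    double v = 6.0;
    if (i == 0 || i == n - 1) v = 1.0;
    else if (i == 1 || i == n - 2) v = 5.0;
    p0[i] = lambda * v;
  }
  for (int i = 0; i < n - 1; ++i) {
    double v = -4.0;
    if (i == 0 || i == n - 2) v = -2.0;
    p1[i] = lambda * v;
  }
  for (int i = 0; i < n - 2; ++i) p2[i] = lambda * 1.0;

  std::vector<double> d0(n), b(n), w(n), w_new(n), y(n);
  std::vector<double> dd(n), l1(n, 0.0), l2(n, 0.0);
  std::vector<double> rhs(n), resid(n);
  // A x for pentadiagonal A given by (d0, p1, p2)
  // extended-precision accumulation: the refinement residual must be
  // computed more accurately than the working precision to be useful on a
  // system whose condition number is ~lambda/p
  auto matvec = [&](const std::vector<double>& x, std::vector<double>& out) {
    for (int j = 0; j < n; ++j) {
      long double v = (long double)d0[j] * x[j];
      if (j >= 1) v += (long double)p1[j - 1] * x[j - 1];
      if (j + 1 < n) v += (long double)p1[j] * x[j + 1];
      if (j >= 2) v += (long double)p2[j - 2] * x[j - 2];
      if (j + 2 < n) v += (long double)p2[j] * x[j + 2];
      out[j] = (double)((long double)rhs[j] - v);
    }
  };
  for (int r = 0; r < nr; ++r) {
    for (int j = 0; j < n; ++j) { y[j] = Y(r, j); w[j] = 1.0; }
    for (int it = 0; it < max_iter; ++it) {
      for (int j = 0; j < n; ++j) {
        d0[j] = p0[j] + w[j];
        b[j] = w[j] * y[j];
        rhs[j] = b[j];
      }
      penta_solve(d0, p1, p2, b, dd, l1, l2); // b now holds z
      // iterative refinement: the system is ill-conditioned
      // (lambda/p spans ~8 orders of magnitude)
      for (int ref = 0; ref < 2; ++ref) {
        matvec(b, resid); // resid = rhs - A b in extended precision
        for (int j = 0; j < n; ++j) { // reuse the factorization
          double v = resid[j];
          if (j >= 1) v -= l1[j - 1] * resid[j - 1];
          if (j >= 2) v -= l2[j - 2] * resid[j - 2];
          resid[j] = v;
        }
        for (int j = 0; j < n; ++j) resid[j] /= dd[j];
        for (int j = n - 1; j >= 0; --j) {
          double v = resid[j];
          if (j + 1 < n) v -= l1[j] * resid[j + 1];
          if (j + 2 < n) v -= l2[j] * resid[j + 2];
          resid[j] = v;
        }
        for (int j = 0; j < n; ++j) b[j] += resid[j];
      }
      // residuals at numerical zero: the baseline interpolates the
      // spectrum (affine input), further reweighting only amplifies noise
      double ymax = 0.0, rmax = 0.0;
      for (int j = 0; j < n; ++j) {
        double ay = std::abs(y[j]), ar = std::abs(y[j] - b[j]);
        if (ay > ymax) ymax = ay;
        if (ar > rmax) rmax = ar;
      }
      if (rmax <= 1e-10 * std::max(ymax, 1.0)) break;
      bool changed = false;
      for (int j = 0; j < n; ++j) {
        w_new[j] = (y[j] > b[j]) ? p : 1.0 - p;
        if (w_new[j] != w[j]) changed = true;
      }
      w.swap(w_new);
      if (!changed) break;
    }
    for (int j = 0; j < n; ++j) Z(r, j) = b[j];
  }
  return Z;
}
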