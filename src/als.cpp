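// Asymmetric least squares baseline: minimize
//   sum_i w_i (y_i - z_i)^2 + lambda * sum (second difference of z)^2
// with w_i = p where y_i > z_i and 1 - p otherwise, weights re-estimated for
// a fixed number of iterations. The normal equations are pentadiagonal and
// solved with a banded Cholesky factorization.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static void penta_solve(const std::vector<double>& d0,
                        const std::vector<double>& d1,
                        const std::vector<double>& d2,
                        const std::vector<double>& b,
                        std::vector<double>& z) {
  const int n = (int)d0.size();
  std::vector<double> L0(n), L1(n > 1 ? n - 1 : 0), L2(n > 2 ? n - 2 : 0);
  for (int i = 0; i < n; ++i) {
    double l2 = 0, l1 = 0;
    if (i >= 2) l2 = d2[i - 2] / L0[i - 2];
    if (i >= 1) {
      double s = d1[i - 1];
      if (i >= 2) s -= l2 * L0[i - 2] * L1[i - 2];
      l1 = s / L0[i - 1];
    }
    double s = d0[i];
    if (i >= 1) s -= l1 * l1 * L0[i - 1];
    if (i >= 2) s -= l2 * l2 * L0[i - 2];
    if (i >= 2) L2[i - 2] = l2;
    if (i >= 1) L1[i - 1] = l1;
    L0[i] = s;
  }
  // LDL^T solve: forward, scale, backward (unit lower triangular L)
  std::vector<double>& y = z;
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    if (i >= 1) s -= L1[i - 1] * y[i - 1];
    if (i >= 2) s -= L2[i - 2] * y[i - 2];
    y[i] = s;
  }
  for (int i = 0; i < n; ++i) y[i] /= L0[i];
  for (int i = n - 1; i >= 0; --i) {
    double s = y[i];
    if (i + 1 < n) s -= L1[i] * y[i + 1];
    if (i + 2 < n) s -= L2[i] * y[i + 2];
    y[i] = s;
  }
}

// [[Rcpp::export]]
NumericVector cpp_als_baseline(NumericVector y, double lambda, double p,
                               int iterations) {
  const int n = y.size();
  if (n < 3) stop("spectrum too short for a second-difference penalty");
  std::vector<double> w(n, 1.0), z(n, 0.0), d0(n), d1(n - 1), d2(n - 2), rhs(n);
  std::vector<double> p0(n), p1(n - 1), p2(n - 2);
  std::fill(p0.begin(), p0.end(), 0.0);
  std::fill(p1.begin(), p1.end(), 0.0);
  std::fill(p2.begin(), p2.end(), 0.0);
  for (int k = 0; k + 2 < n; ++k) { // rows of D (1, -2, 1)
    p0[k] += lambda; p0[k + 1] += 4 * lambda; p0[k + 2] += lambda;
    p1[k] += -2 * lambda; p1[k + 1] += -2 * lambda;
    p2[k] += lambda;
  }
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) { d0[i] = p0[i] + w[i]; rhs[i] = w[i] * y[i]; }
    for (int i = 0; i + 1 < n; ++i) d1[i] = p1[i];
    for (int i = 0; i + 2 < n; ++i) d2[i] = p2[i];
    penta_solve(d0, d1, d2, rhs, z);
    for (int i = 0; i < n; ++i) w[i] = (y[i] > z[i]) ? p : 1.0 - p;
  }
  return NumericVector(z.begin(), z.end());
}
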