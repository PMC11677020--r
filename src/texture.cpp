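// Dense-loop texture descriptors: rotation-invariant uniform LBP with local
// variance, LPQ (short-term Fourier phase codes, separable window) and the
// gray-level co-occurrence tally. Windowed operators use the valid interior
// region only. Hot loops work on raw buffers with precomputed offsets.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Rotation-invariant uniform LBP histogram (P + 2 bins) plus the mean and sd
// of the local neighbour variance (VAR_{P,R}) over the valid region.
// Neighbour k sits at (row - R sin a_k, col + R cos a_k), a_k = 2 pi k / P,
// sampled with bilinear interpolation; comparisons use >= center with a small
// rounding guard so exact ties count as 1.
// [[Rcpp::export]]
List cpp_lbp(NumericMatrix img, int P, double R) {
  const int nr = img.nrow(), nc = img.ncol();
  const int m = (int)std::ceil(R);
  if (nr < 2 * m + 1 || nc < 2 * m + 1)
    stop("image smaller than the LBP neighbourhood");
  const double* px = &img(0, 0);

  // precompute, per neighbour: the four bilinear support offsets and
  // weights (constant across pixels); integral offsets collapse their
  // support so no out-of-neighbourhood pixel is ever touched
  std::vector<long> o00(P), o10(P), o01(P), o11(P);
  std::vector<double> w00(P), w01(P), w10(P), w11(P);
  for (int k = 0; k < P; ++k) {
    double a = 2.0 * M_PI * k / P;
    double dr = -R * std::sin(a), dc = R * std::cos(a);
    if (std::fabs(dr - std::round(dr)) < 1e-9) dr = std::round(dr);
    if (std::fabs(dc - std::round(dc)) < 1e-9) dc = std::round(dc);
    double fr = dr - std::floor(dr), fc = dc - std::floor(dc);
    long r0 = (long)std::floor(dr), c0 = (long)std::floor(dc);
    long r1 = r0 + (fr > 0 ? 1 : 0), c1 = c0 + (fc > 0 ? 1 : 0);
    o00[k] = r0 + c0 * (long)nr;
    o10[k] = r1 + c0 * (long)nr;
    o01[k] = r0 + c1 * (long)nr;
    o11[k] = r1 + c1 * (long)nr;
    w00[k] = (1 - fr) * (1 - fc);
    w10[k] = fr * (1 - fc);
    w01[k] = (1 - fr) * fc;
    w11[k] = fr * fc;
  }

  NumericVector hist(P + 2);
  double vs = 0, vs2 = 0;
  long ncount = 0;
  std::vector<double> v(P);
  const double eps = 1e-9;
  for (int j = m; j < nc - m; ++j) {
    for (int i = m; i < nr - m; ++i) {
      const double* c = px + i + (long)j * nr;
      double ctr = *c;
      double mu = 0;
      for (int k = 0; k < P; ++k) {
        double val = w00[k] * c[o00[k]] + w10[k] * c[o10[k]] +
                     w01[k] * c[o01[k]] + w11[k] * c[o11[k]];
        v[k] = val;
        mu += val;
      }
      mu /= P;
      double var = 0;
      int ones = 0, trans = 0, prev = 0, first = 0;
      for (int k = 0; k < P; ++k) {
        double d = v[k] - mu;
        var += d * d;
        int b = (v[k] >= ctr - eps) ? 1 : 0;
        ones += b;
        if (k == 0) first = b; else trans += (b != prev);
        prev = b;
      }
      trans += (prev != first);
      var /= P;
      hist[(trans <= 2) ? ones : (P + 1)] += 1.0;
      vs += var; vs2 += var * var;
      ++ncount;
    }
  }
  for (int b = 0; b < P + 2; ++b) hist[b] /= (double)ncount;
  double vmean = vs / ncount;
  double vvar = vs2 / ncount - vmean * vmean;
  return List::create(_["hist"] = hist, _["varMean"] = vmean,
                      _["varSd"] = std::sqrt(vvar > 0 ? vvar : 0));
}

// LPQ: 8-bit codes from the signs of Re/Im of four low-frequency STFT
// coefficients (uniform window of side w, frequency a = 1/w):
// u1 = (a, 0), u2 = (0, a), u3 = (a, a), u4 = (a, -a), where the first
// component runs along columns (x) and the second along rows (y).
// Basis functions are separable; bit order (LSB first):
// Re u1, Im u1, Re u2, Im u2, Re u3, Im u3, Re u4, Im u4; bit = (value > 0).
// Returns the normalized 256-bin code histogram over the valid region.
// [[Rcpp::export]]
NumericVector cpp_lpq(NumericMatrix img, int w) {
  const int nr = img.nrow(), nc = img.ncol();
  if (nr < w || nc < w) stop("image side smaller than the LPQ window");
  const int m = w / 2;
  const double a = 1.0 / w;
  std::vector<double> er(w), ei(w);
  for (int x = -m; x <= m; ++x) {
    er[x + m] = std::cos(-2.0 * M_PI * a * x);
    ei[x + m] = std::sin(-2.0 * M_PI * a * x);
  }
  const double* px = &img(0, 0);
  const int vr = nr - 2 * m, vc = nc - 2 * m;

  // row pass: sum over the column offset (x direction) for basis 1 and w0
  std::vector<double> s0((size_t)nr * vc), s1r((size_t)nr * vc),
      s1i((size_t)nr * vc);
  for (int j = 0; j < vc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double* b = px + i + (long)j * nr;
      double a0 = 0, ar = 0, ai = 0;
      for (int x = 0; x < w; ++x) {
        double val = b[(long)x * nr];
        a0 += val;
        ar += val * er[x];
        ai += val * ei[x];
      }
      size_t k = i + (size_t)j * nr;
      s0[k] = a0; s1r[k] = ar; s1i[k] = ai;
    }
  }
  NumericVector hist(256);
  for (int j = 0; j < vc; ++j) {
    const double* q0 = s0.data() + (size_t)j * nr;
    const double* q1r = s1r.data() + (size_t)j * nr;
    const double* q1i = s1i.data() + (size_t)j * nr;
    for (int i = 0; i < vr; ++i) {
      double F1r = 0, F1i = 0, F2r = 0, F2i = 0, F3r = 0, F3i = 0,
             F4r = 0, F4i = 0;
      for (int y = 0; y < w; ++y) {
        double c = er[y], s = ei[y];
        double v0 = q0[i + y], vr1 = q1r[i + y], vi1 = q1i[i + y];
        F1r += vr1;             F1i += vi1;              // (a, 0)
        F2r += v0 * c;          F2i += v0 * s;           // (0, a)
        F3r += vr1 * c - vi1 * s; F3i += vr1 * s + vi1 * c; // (a, a)
        F4r += vr1 * c + vi1 * s; F4i += vi1 * c - vr1 * s; // (a, -a)
      }
      int code = (F1r > 0) | ((F1i > 0) << 1) | ((F2r > 0) << 2) |
                 ((F2i > 0) << 3) | ((F3r > 0) << 4) | ((F3i > 0) << 5) |
                 ((F4r > 0) << 6) | ((F4i > 0) << 7);
      hist[code] += 1.0;
    }
  }
  double tot = (double)vr * vc;
  for (int b = 0; b < 256; ++b) hist[b] /= tot;
  return hist;
}

// Co-occurrence counts of quantized levels (0-based) at offset (dr, dc).
// Asymmetric tally; normalization happens in R.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerMatrix q, int levels, int dr, int dc) {
  const int nr = q.nrow(), nc = q.ncol();
  const int* px = &q(0, 0);
  for (long k = 0; k < (long)nr * nc; ++k)
    if (px[k] < 0 || px[k] >= levels) stop("quantized level out of range");
  std::vector<double> M((size_t)levels * levels, 0.0);
  const int i0 = std::max(0, -dr), i1 = std::min(nr, nr - dr);
  const int j0 = std::max(0, -dc), j1 = std::min(nc, nc - dc);
  const long shift = dr + (long)dc * nr;
  for (int j = j0; j < j1; ++j) {
    const int* b = px + (long)j * nr;
    for (int i = i0; i < i1; ++i)
      M[b[i] + (size_t)levels * b[i + shift]] += 1.0;
  }
  NumericMatrix out(levels, levels);
  std::copy(M.begin(), M.end(), out.begin());
  return out;
}

// single-pass finiteness check without allocations
// [[Rcpp::export]]
bool cpp_all_finite(NumericMatrix x) {
  const double* p = &x(0, 0);
  const long n = (long)x.nrow() * x.ncol();
  for (long k = 0; k < n; ++k)
    if (!std::isfinite(p[k])) return false;
  return true;
}

// linear min-max rescale to 0 .. levels-1 integer gray levels
// [[Rcpp::export]]
IntegerMatrix cpp_quantize(NumericMatrix x, int levels) {
  const int nr = x.nrow(), nc = x.ncol();
  const double* p = &x(0, 0);
  const long n = (long)nr * nc;
  double lo = p[0], hi = p[0];
  for (long k = 1; k < n; ++k) {
    if (p[k] < lo) lo = p[k];
    if (p[k] > hi) hi = p[k];
  }
  IntegerMatrix q(nr, nc);
  int* qp = &q(0, 0);
  if (hi <= lo) { std::fill(qp, qp + n, 0); return q; }
  const double s = levels / (hi - lo);
  for (long k = 0; k < n; ++k) {
    int v = (int)((p[k] - lo) * s);
    qp[k] = v >= levels ? levels - 1 : v;
  }
  return q;
}
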