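// FFT-backed image kernels: Gabor filter-bank statistics and anisotropic
// Gaussian filtering of random fields (speckle / fibrous texture synthesis).
// Single-precision FFTW is used; images are R column-major matrices, so the
// FFTW plan is created with dimensions (ncol, nrow).

#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::complex<float> cfloat;

static inline double fftfreq(int k, int n) {
  return (k <= n / 2 ? (double)k : (double)(k - n)) / (double)n;
}

static void fft2_inplace(std::vector<cfloat>& buf, int nr, int nc, int sign) {
  fftwf_plan p = fftwf_plan_dft_2d(
      nc, nr, reinterpret_cast<fftwf_complex*>(buf.data()),
      reinterpret_cast<fftwf_complex*>(buf.data()), sign, FFTW_ESTIMATE);
  fftwf_execute(p);
  fftwf_destroy_plan(p);
}

// Mean and sd of the complex Gabor response magnitude for every filter in a
// polar frequency-domain bank. Filters are Gaussian in radial frequency
// (sigma_r = radialSigmaFactor * f0) and in angle (angularSigma, radians),
// one-sided (analytic), with the DC bin forced to zero. Periodic boundary.
// Returns a 2 x (length(freqs)*length(thetas)) matrix [mean; sd], filters
// ordered band-major with orientation varying fastest.
// [[Rcpp::export]]
NumericMatrix cpp_gabor_stats(NumericMatrix img, NumericVector freqs,
                              NumericVector thetasDeg,
                              double radialSigmaFactor, double angularSigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nf = freqs.size(), nt = thetasDeg.size();
  const double N = (double)nr * (double)nc;

  std::vector<cfloat> F((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      F[i + (size_t)j * nr] = cfloat((float)img(i, j), 0.0f);
  fft2_inplace(F, nr, nc, FFTW_FORWARD);

  // polar coordinates of the frequency grid
  std::vector<float> rad((size_t)nr * nc), ang((size_t)nr * nc);
  for (int j = 0; j < nc; ++j) {
    double fx = fftfreq(j, nc);
    for (int i = 0; i < nr; ++i) {
      double fy = fftfreq(i, nr);
      size_t k = i + (size_t)j * nr;
      rad[k] = (float)std::sqrt(fx * fx + fy * fy);
      ang[k] = (float)std::atan2(fy, fx);
    }
  }

  NumericMatrix out(2, nf * nt);
  std::vector<cfloat> W((size_t)nr * nc);

  for (int fi = 0; fi < nf; ++fi) {
    const float f0 = (float)freqs[fi];
    const float sr = (float)(radialSigmaFactor * freqs[fi]);
    const float sa = (float)angularSigma;
    // a band whose 4-sigma radial support stays below half Nyquist can be
    // evaluated on the half-resolution frequency grid: the inverse FFT then
    // returns the exact filter response at every second pixel, whose
    // magnitude statistics estimate the same quantities
    int mr = nr, mc = nc;
    if (f0 + 4.0f * sr < 0.25f && nr % 2 == 0 && nc % 2 == 0) {
      mr = nr / 2; mc = nc / 2;
    }
    const double M = (double)mr * (double)mc;
    for (int ti = 0; ti < nt; ++ti) {
      const float th = (float)(thetasDeg[ti] * M_PI / 180.0);
      for (int j = 0; j < mc; ++j) {
        int js = (j < (mc + 1) / 2) ? j : j + (nc - mc);
        for (int i = 0; i < mr; ++i) {
          int is = (i < (mr + 1) / 2) ? i : i + (nr - mr);
          size_t ks = is + (size_t)js * nr;
          size_t kd = i + (size_t)j * mr;
          float dr = (rad[ks] - f0) / sr;
          if (std::fabs(dr) > 4.0f) { W[kd] = cfloat(0.f, 0.f); continue; }
          float da = ang[ks] - th;
          while (da > (float)M_PI) da -= 2.0f * (float)M_PI;
          while (da < -(float)M_PI) da += 2.0f * (float)M_PI;
          da /= sa;
          if (std::fabs(da) > 4.0f) { W[kd] = cfloat(0.f, 0.f); continue; }
          float g = std::exp(-0.5f * (dr * dr + da * da));
          W[kd] = F[ks] * g;
        }
      }
      W[0] = cfloat(0.f, 0.f); // DC-free
      fft2_inplace(W, mr, mc, FFTW_BACKWARD);
      double s = 0.0, s2 = 0.0;
      for (size_t k = 0; k < (size_t)mr * mc; ++k) {
        double m = std::abs(W[k]) / N;
        s += m; s2 += m * m;
      }
      double mean = s / M;
      double var = s2 / M - mean * mean;
      int col = fi * nt + ti;
      out(0, col) = mean;
      out(1, col) = std::sqrt(var > 0 ? var : 0);
    }
  }
  return out;
}

// Filter a real field with a Gaussian blur of sd sigmaAlong (pixels) along
// spatial direction thetaDeg and sigmaAcross across it, realised in the
// frequency domain (periodic boundary). Used by the enface-image generator.
// [[Rcpp::export]]
NumericMatrix cpp_aniso_gauss_filter(NumericMatrix x, double sigmaAlong,
                                     double sigmaAcross, double thetaDeg) {
  const int nr = x.nrow(), nc = x.ncol();
  const double N = (double)nr * (double)nc;
  const double th = thetaDeg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double ka = 2.0 * M_PI * M_PI * sigmaAlong * sigmaAlong;
  const double kc = 2.0 * M_PI * M_PI * sigmaAcross * sigmaAcross;

  std::vector<cfloat> F((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      F[i + (size_t)j * nr] = cfloat((float)x(i, j), 0.0f);
  fft2_inplace(F, nr, nc, FFTW_FORWARD);

  for (int j = 0; j < nc; ++j) {
    double fx = fftfreq(j, nc);
    for (int i = 0; i < nr; ++i) {
      double fy = fftfreq(i, nr);
      double fa = fx * ct + fy * st;   // frequency component along theta
      double fc = -fx * st + fy * ct;
      double e = ka * fa * fa + kc * fc * fc;
      float h = (e > 60.0) ? 0.0f : (float)std::exp(-e);
      F[i + (size_t)j * nr] *= h;
    }
  }
  fft2_inplace(F, nr, nc, FFTW_BACKWARD);

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = F[i + (size_t)j * nr].real() / N;
  return out;
}

// Spectral energy binned by polar angle (degrees, modulo 180), for testing
// orientation content of generated textures. DC excluded.
// [[Rcpp::export]]
NumericVector cpp_angular_energy(NumericMatrix img, int nbins) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<cfloat> F((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      F[i + (size_t)j * nr] = cfloat((float)img(i, j), 0.0f);
  fft2_inplace(F, nr, nc, FFTW_FORWARD);
  NumericVector out(nbins);
  for (int j = 0; j < nc; ++j) {
    double fx = fftfreq(j, nc);
    for (int i = 0; i < nr; ++i) {
      if (i == 0 && j == 0) continue;
      double fy = fftfreq(i, nr);
      double a = std::atan2(fy, fx) * 180.0 / M_PI;
      a -= 180.0 * std::floor(a / 180.0); // wrap into [0, 180)
      int b = (int)(a / (180.0 / nbins));
      if (b >= nbins) b = nbins - 1;
      double m = std::abs(F[i + (size_t)j * nr]);
      out[b] += m * m;
    }
  }
  return out;
}

// One-call enface texture synthesis. Speckle: the amplitude of a complex
// Gaussian field with isotropic Gaussian correlation (z1 + i z2 filtered in
// one packed FFT; the frequency response is real and even, so real and
// imaginary parts stay independent). Optional fibrous component: zf blurred
// along spatial direction thetaDeg (sd sigmaAlong) and across (sigmaAcross),
// standardized and added with 'weight' times the mean speckle amplitude.
// Output is min-max scaled to [0, 1].
// [[Rcpp::export]]
NumericMatrix cpp_enface_texture(NumericMatrix z1, NumericMatrix z2,
                                 double speckleSigma,
                                 Nullable<NumericMatrix> zf,
                                 double sigmaAlong, double sigmaAcross,
                                 double thetaDeg, double weight) {
  const int nr = z1.nrow(), nc = z1.ncol();
  const double N = (double)nr * (double)nc;
  const double ks = 2.0 * M_PI * M_PI * speckleSigma * speckleSigma;

  std::vector<cfloat> F((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      F[i + (size_t)j * nr] = cfloat((float)z1(i, j), (float)z2(i, j));
  fft2_inplace(F, nr, nc, FFTW_FORWARD);
  for (int j = 0; j < nc; ++j) {
    double fx = fftfreq(j, nc);
    for (int i = 0; i < nr; ++i) {
      double fy = fftfreq(i, nr);
      double e = ks * (fx * fx + fy * fy);
      F[i + (size_t)j * nr] *= (e > 60.0) ? 0.0f : (float)std::exp(-e);
    }
  }
  fft2_inplace(F, nr, nc, FFTW_BACKWARD);

  NumericMatrix out(nr, nc);
  double sum = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = std::abs(F[i + (size_t)j * nr]) / N;
      out(i, j) = a;
      sum += a;
    }
  double meanAmp = sum / N;

  if (zf.isNotNull() && weight != 0) {
    NumericMatrix zfm(zf);
    const double th = thetaDeg * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    const double ka = 2.0 * M_PI * M_PI * sigmaAlong * sigmaAlong;
    const double kc = 2.0 * M_PI * M_PI * sigmaAcross * sigmaAcross;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        F[i + (size_t)j * nr] = cfloat((float)zfm(i, j), 0.0f);
    fft2_inplace(F, nr, nc, FFTW_FORWARD);
    for (int j = 0; j < nc; ++j) {
      double fx = fftfreq(j, nc);
      for (int i = 0; i < nr; ++i) {
        double fy = fftfreq(i, nr);
        double fa = fx * ct + fy * st, fc = -fx * st + fy * ct;
        double e = ka * fa * fa + kc * fc * fc;
        F[i + (size_t)j * nr] *= (e > 60.0) ? 0.0f : (float)std::exp(-e);
      }
    }
    fft2_inplace(F, nr, nc, FFTW_BACKWARD);
    double fs = 0.0, fs2 = 0.0;
    for (size_t k = 0; k < F.size(); ++k) {
      double v = F[k].real() / N;
      fs += v; fs2 += v * v;
    }
    double fmean = fs / N;
    double fsd = std::sqrt(std::max(fs2 / N - fmean * fmean, 1e-300));
    double w = weight * meanAmp / fsd;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        out(i, j) += w * (F[i + (size_t)j * nr].real() / N - fmean);
  }

  double lo = out(0, 0), hi = out(0, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = out(i, j);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
  if (hi > lo)
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        out(i, j) = (out(i, j) - lo) / (hi - lo);
  return out;
}
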