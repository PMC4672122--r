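#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 2D median filter with replicate padding; window must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int window) {
  const int h = img.nrow(), w = img.ncol(), r = window / 2;
  NumericMatrix out(h, w);
  std::vector<double> buf(window * window);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int k = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = clampi(j + dj, 0, w - 1);
        for (int di = -r; di <= r; ++di) {
          int ii = clampi(i + di, 0, h - 1);
          buf[k++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// Perona-Malik anisotropic diffusion, explicit scheme, exponential
// conductance g(|d|) = exp(-(d/kappa)^2), zero-flux borders.
// Stable for dt <= 0.25 (4-neighbour stencil).
// [[Rcpp::export]]
NumericMatrix cpp_pm_diffuse(const NumericMatrix& img, int iterations,
                             double kappa, double dt) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix cur = clone(img);
  NumericMatrix nxt(h, w);
  const double k2 = kappa * kappa;
  for (int it = 0; it < iterations; ++it) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double c = cur(i, j);
        double dN = (i > 0     ? cur(i - 1, j) : c) - c;
        double dS = (i < h - 1 ? cur(i + 1, j) : c) - c;
        double dW = (j > 0     ? cur(i, j - 1) : c) - c;
        double dE = (j < w - 1 ? cur(i, j + 1) : c) - c;
        double flux = dN * std::exp(-(dN * dN) / k2)
                    + dS * std::exp(-(dS * dS) / k2)
                    + dW * std::exp(-(dW * dW) / k2)
                    + dE * std::exp(-(dE * dE) / k2);
        nxt(i, j) = c + dt * flux;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Separable convolution with replicate padding. ky runs over rows,
// kx over columns; both kernels are centred (odd length).
// [[Rcpp::export]]
NumericMatrix cpp_sep_convolve(const NumericMatrix& img,
                               const NumericVector& ky,
                               const NumericVector& kx) {
  const int h = img.nrow(), w = img.ncol();
  const int ry = ky.size() / 2, rx = kx.size() / 2;
  NumericMatrix tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0;
      for (int t = -ry; t <= ry; ++t)
        s += ky[t + ry] * img(clampi(i + t, 0, h - 1), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0;
      for (int t = -rx; t <= rx; ++t)
        s += kx[t + rx] * tmp(i, clampi(j + t, 0, w - 1));
      out(i, j) = s;
    }
  return out;
}

// Full (non-separable) 2D convolution with replicate padding; kernel
// must have odd dimensions. Correlation orientation (no kernel flip),
// which is what the symmetric smoothing kernels here require.
// [[Rcpp::export]]
NumericMatrix cpp_convolve2(const NumericMatrix& img,
                            const NumericMatrix& kern) {
  const int h = img.nrow(), w = img.ncol();
  const int ry = kern.nrow() / 2, rx = kern.ncol() / 2;
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0;
      for (int dj = -rx; dj <= rx; ++dj)
        for (int di = -ry; di <= ry; ++di)
          s += kern(di + ry, dj + rx) *
               img(clampi(i + di, 0, h - 1), clampi(j + dj, 0, w - 1));
      out(i, j) = s;
    }
  return out;
}

// Exact Otsu threshold of a set of values: candidate thresholds are the
// distinct observed values t; classes {x < t} and {x >= t}; maximises
// the between-class variance w0*w1*(mu0-mu1)^2. Ties keep the smallest
// threshold. Returns NA when all values are equal (degenerate window).
static double otsu_exact(std::vector<double>& v) {
  std::sort(v.begin(), v.end());
  const int n = (int)v.size();
  if (v.front() == v.back()) return NA_REAL;
  std::vector<double> cum(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cum[i + 1] = cum[i] + v[i];
  double best = -1.0, bestT = v.back();
  for (int k = 1; k < n; ++k) {        // first k values below threshold v[k]
    if (v[k] == v[k - 1]) continue;    // not a distinct candidate
    double w0 = (double)k / n, w1 = 1.0 - w0;
    double mu0 = cum[k] / k, mu1 = (cum[n] - cum[k]) / (n - k);
    double bcv = w0 * w1 * (mu0 - mu1) * (mu0 - mu1);
    if (bcv > best) { best = bcv; bestT = v[k]; }
  }
  return bestT;
}

// Tiled local Otsu binarisation: the image is partitioned into
// window x window tiles; each tile is thresholded with the exact Otsu
// rule above (pixel >= threshold -> foreground). Degenerate tiles --
// constant intensity, or a between-class mean separation below
// min_contrast (tiles containing only background noise) -- become
// background.
// [[Rcpp::export]]
IntegerMatrix cpp_local_otsu(const NumericMatrix& img, int window,
                             double min_contrast) {
  const int h = img.nrow(), w = img.ncol();
  IntegerMatrix out(h, w);
  for (int j0 = 0; j0 < w; j0 += window) {
    int j1 = std::min(j0 + window, w);
    for (int i0 = 0; i0 < h; i0 += window) {
      int i1 = std::min(i0 + window, h);
      std::vector<double> v;
      v.reserve((i1 - i0) * (j1 - j0));
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i) v.push_back(img(i, j));
      double t = otsu_exact(v);
      if (ISNA(t)) continue;           // degenerate -> background
      double s0 = 0, s1 = 0;
      int n0 = 0, n1 = 0;
      for (double x : v) {
        if (x < t) { s0 += x; ++n0; } else { s1 += x; ++n1; }
      }
      if (n0 > 0 && n1 > 0 && (s1 / n1 - s0 / n0) < min_contrast)
        continue;                      // noise-only tile -> background
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i)
          if (img(i, j) >= t) out(i, j) = 1;
    }
  }
  return out;
}

// Isolated point-set removal: a positive pixel survives iff its 3x3
// neighbourhood contains more than n positive pixels. By default the
// centre pixel is excluded from the count; include_center flips that.
// Pixels outside the image count as background.
// [[Rcpp::export]]
IntegerMatrix cpp_remove_isolated(const IntegerMatrix& mask, int n,
                                  bool include_center) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j)) continue;
      int cnt = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!include_center && di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
          cnt += mask(ii, jj);
        }
      if (cnt > n) out(i, j) = 1;
    }
  return out;
}
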