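#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Binary dilation, set definition: x is in A (+) B iff the reflection
// of B translated to x intersects A. Pixels outside the frame are
// background. Offsets are (dy, dx) rows of `off`.
// [[Rcpp::export]]
IntegerMatrix cpp_binary_dilate(const IntegerMatrix& mask,
                                const IntegerMatrix& off) {
  const int h = mask.nrow(), w = mask.ncol(), K = off.nrow();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      for (int k = 0; k < K; ++k) {
        int ii = i - off(k, 0), jj = j - off(k, 1);  // reflected SE
        if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
        if (mask(ii, jj)) { out(i, j) = 1; break; }
      }
    }
  return out;
}

// Binary erosion: x is in A (-) B iff B translated to x is contained
// in A. `outside` gives the membership value assumed beyond the frame
// (0 for the foreground set, 1 when eroding a complement whose
// background extends indefinitely).
// [[Rcpp::export]]
IntegerMatrix cpp_binary_erode(const IntegerMatrix& mask,
                               const IntegerMatrix& off, int outside) {
  const int h = mask.nrow(), w = mask.ncol(), K = off.nrow();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      int fit = 1;
      for (int k = 0; k < K; ++k) {
        int ii = i + off(k, 0), jj = j + off(k, 1);
        int v = (ii < 0 || ii >= h || jj < 0 || jj >= w) ? outside
                                                         : mask(ii, jj);
        if (!v) { fit = 0; break; }
      }
      out(i, j) = fit;
    }
  return out;
}

// Gray-scale erosion by a weighted SE b over domain offsets `off`
// with values `val`: (f (-) b)(s,t) = min_x f(s+x, t+y) - b(x,y).
// Replicate padding at the borders.
// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& f,
                             const IntegerMatrix& off,
                             const NumericVector& val) {
  const int h = f.nrow(), w = f.ncol(), K = off.nrow();
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int ii = clampi(i + off(k, 0), 0, h - 1);
        int jj = clampi(j + off(k, 1), 0, w - 1);
        double v = f(ii, jj) - val[k];
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

// Gray-scale dilation: (f (+) b)(s,t) = max_x f(s-x, t-y) + b(x,y).
// Replicate padding.
// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& f,
                              const IntegerMatrix& off,
                              const NumericVector& val) {
  const int h = f.nrow(), w = f.ncol(), K = off.nrow();
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ii = clampi(i - off(k, 0), 0, h - 1);
        int jj = clampi(j - off(k, 1), 0, w - 1);
        double v = f(ii, jj) + val[k];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

// Gray-scale Hit-Miss map: at every position p,
//   net_h(p) = min_x a(p+x) - t_hit(x)
//   net_m(p) = max_x a(p+x) - t_miss(x)   (t_miss stored as applied,
//                                          i.e. already reflected)
//   out(p)   = net_h(p) - net_m(p).
// Replicate padding; argmin/argmax offset indices (1-based, first
// raster-order winner on ties) are returned for subgradient routing.
// [[Rcpp::export]]
List cpp_hit_miss_map(const NumericMatrix& a, const IntegerMatrix& off,
                      const NumericVector& hit, const NumericVector& miss) {
  const int h = a.nrow(), w = a.ncol(), K = off.nrow();
  NumericMatrix out(h, w);
  IntegerMatrix argh(h, w), argm(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double mh = R_PosInf, mm = R_NegInf;
      int kh = 0, km = 0;
      for (int k = 0; k < K; ++k) {
        int ii = clampi(i + off(k, 0), 0, h - 1);
        int jj = clampi(j + off(k, 1), 0, w - 1);
        double v = a(ii, jj);
        double vh = v - hit[k];
        double vm = v - miss[k];
        if (vh < mh) { mh = vh; kh = k; }
        if (vm > mm) { mm = vm; km = k; }
      }
      out(i, j) = mh - mm;
      argh(i, j) = kh + 1;
      argm(i, j) = km + 1;
    }
  return List::create(_["map"] = out, _["arg_hit"] = argh,
                      _["arg_miss"] = argm);
}
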