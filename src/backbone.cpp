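// Wavelet modulus-maxima contour detection and conditional symmetric
// pairing used for dendrite backbone extraction.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static double bilinear(const NumericMatrix& m, double y, double x) {
  const int h = m.nrow(), w = m.ncol();
  y = std::min(std::max(y, 0.0), (double)(h - 1));
  x = std::min(std::max(x, 0.0), (double)(w - 1));
  int i0 = (int)std::floor(y), j0 = (int)std::floor(x);
  int i1 = std::min(i0 + 1, h - 1), j1 = std::min(j0 + 1, w - 1);
  double fy = y - i0, fx = x - j0;
  return (1 - fy) * ((1 - fx) * m(i0, j0) + fx * m(i0, j1)) +
         fy * ((1 - fx) * m(i1, j0) + fx * m(i1, j1));
}

// Non-maximum suppression along the gradient direction: keep pixels
// whose modulus exceeds the threshold and is >= the modulus bilinearly
// interpolated one pixel along +/- the unit gradient direction.
// Returns an n x 2 matrix of 1-based (row, col) contour points.
// [[Rcpp::export]]
IntegerMatrix cpp_modulus_maxima(const NumericMatrix& wx,
                                 const NumericMatrix& wy,
                                 const NumericMatrix& mod,
                                 double threshold) {
  const int h = mod.nrow(), w = mod.ncol();
  std::vector<int> ri, ci;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double mv = mod(i, j);
      if (mv <= threshold || mv <= 0) continue;
      double uy = wy(i, j) / mv, ux = wx(i, j) / mv;
      double m1 = bilinear(mod, i + uy, j + ux);
      double m2 = bilinear(mod, i - uy, j - ux);
      // strict on the uphill side breaks the two-pixel tie a symmetric
      // discrete edge produces (keeping the interior pixel of the
      // pair); the epsilon absorbs round-off between mirror-image
      // convolution sums
      double eps = 1e-9 * mv;
      if (mv > m1 + eps && mv >= m2 - eps) {
        ri.push_back(i + 1); ci.push_back(j + 1);
      }
    }
  IntegerMatrix out(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) { out(k, 0) = ri[k]; out(k, 1) = ci[k]; }
  return out;
}

// Conditional symmetric pairing. For each contour point p, march along
// its unit gradient direction (uphill, i.e. into the bright stroke) up
// to max_march pixels; the first contour point q encountered whose
// gradient is approximately opposite (angle within angle_tol of pi) and
// whose separation |q - p| matches the scale s within tol is accepted.
// The pair is kept only if its midpoint lies in the foreground mask.
// points: n x 2 (row, col), 1-based. Returns a list of matched pairs.
// [[Rcpp::export]]
List cpp_pair_points(const IntegerMatrix& points, const NumericMatrix& wx,
                     const NumericMatrix& wy, const IntegerMatrix& mask,
                     double s, double tol, double angle_tol,
                     double max_march) {
  const int h = mask.nrow(), w = mask.ncol(), n = points.nrow();
  // lookup grid: contour point index at each pixel (-1 when none)
  std::vector<int> grid((size_t)h * w, -1);
  for (int k = 0; k < n; ++k)
    grid[(points(k, 0) - 1) + (size_t)(points(k, 1) - 1) * h] = k;
  const double cos_tol = std::cos(M_PI - angle_tol);  // dot <= cos_tol
  std::vector<double> pr, pc, qr, qc, sep, wproj;
  for (int k = 0; k < n; ++k) {
    int i = points(k, 0) - 1, j = points(k, 1) - 1;
    double gx = wx(i, j), gy = wy(i, j);
    double gm = std::sqrt(gx * gx + gy * gy);
    if (gm <= 0) continue;
    double uy = gy / gm, ux = gx / gm;
    int best = -1;
    for (double t = 1.0; t <= max_march && best < 0; t += 0.5) {
      int ci = (int)std::lround(i + t * uy), cj = (int)std::lround(j + t * ux);
      if (ci < 0 || ci >= h || cj < 0 || cj >= w) break;
      // candidate counterparts in the 3x3 neighbourhood of the march
      // position (curved contours drift off the exact ray)
      double bestd = R_PosInf;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = ci + di, jj = cj + dj;
          if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
          int q = grid[ii + (size_t)jj * h];
          if (q < 0 || q == k) continue;
          double qgx = wx(ii, jj), qgy = wy(ii, jj);
          double qgm = std::sqrt(qgx * qgx + qgy * qgy);
          if (qgm <= 0) continue;
          double dot = (gx * qgx + gy * qgy) / (gm * qgm);
          if (dot > cos_tol) continue;           // not an opposite edge
          double dy = ii - i, dx = jj - j;
          double d = std::sqrt(dy * dy + dx * dx);
          if (std::fabs(d - s) > tol) continue;
          if (std::fabs(d - s) < bestd) { bestd = std::fabs(d - s); best = q; }
        }
    }
    if (best < 0) continue;                      // unstable symmetry: discard
    int qi = points(best, 0) - 1, qj = points(best, 1) - 1;
    double my = 0.5 * (i + qi), mx = 0.5 * (j + qj);
    int mi = (int)std::lround(my), mj = (int)std::lround(mx);
    if (!mask(mi, mj)) continue;                 // midpoint must be in foreground
    // width constraint: the separation must match the width of the
    // regular region, measured as the foreground run length through
    // the midpoint along the pairing direction
    double wrun = 1.0;
    for (int sgn = -1; sgn <= 1; sgn += 2) {
      for (double t = 0.5; t <= max_march; t += 0.5) {
        int ii = (int)std::lround(my + sgn * t * uy);
        int jj = (int)std::lround(mx + sgn * t * ux);
        if (ii < 0 || ii >= h || jj < 0 || jj >= w || !mask(ii, jj)) {
          wrun += (t - 0.5);
          break;
        }
        if (t + 0.5 > max_march) wrun += t;
      }
    }
    double dsep = std::sqrt((double)(qi - i) * (qi - i) +
                            (double)(qj - j) * (qj - j));
    if (std::fabs(dsep - wrun) > std::max(1.5, 0.25 * wrun)) continue;
    double dy = qi - i, dx = qj - j;
    pr.push_back(i + 1); pc.push_back(j + 1);
    qr.push_back(qi + 1); qc.push_back(qj + 1);
    sep.push_back(std::sqrt(dy * dy + dx * dx));
    // local stroke width: separation projected on the pairing direction
    wproj.push_back(std::fabs(dy * uy + dx * ux));
  }
  return List::create(_["p_row"] = pr, _["p_col"] = pc, _["q_row"] = qr,
                      _["q_col"] = qc, _["separation"] = sep,
                      _["width"] = wproj);
}

// Zhang-Suen thinning of a binary mask down to an 8-connected,
// one-pixel-wide skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix img = clone(mask);
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= h || j < 0 || j >= w) return 0;
    return img(i, j);
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          if (!img(i, j)) continue;
          int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
              p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back({i, j});
        }
      if (!kill.empty()) changed = true;
      for (auto& pq : kill) img(pq.first, pq.second) = 0;
    }
  }
  return img;
}
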