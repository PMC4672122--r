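#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling of a binary mask (BFS flood fill).
// Labels are 1..ncomp in first-encounter (column-major) order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push({i, j});
      while (!q.empty()) {
        auto pq = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = pq.first + di, jj = pq.second + dj;
            if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push({ii, jj});
            }
          }
      }
    }
  return lab;
}

// Geodesic distance within a binary mask from a start pixel, with
// 8-connected steps weighted 1 (axial) and sqrt(2) (diagonal).
// Unreachable or background pixels get NA. start is 1-based (row, col).
// [[Rcpp::export]]
NumericMatrix cpp_geodesic(const IntegerMatrix& mask, int start_row,
                           int start_col) {
  const int h = mask.nrow(), w = mask.ncol();
  NumericMatrix dist(h, w);
  std::fill(dist.begin(), dist.end(), NA_REAL);
  const int si = start_row - 1, sj = start_col - 1;
  if (si < 0 || si >= h || sj < 0 || sj >= w || !mask(si, sj))
    stop("start pixel is outside the mask");
  typedef std::pair<double, int> Node;  // (dist, pixel index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  dist(si, sj) = 0.0;
  pq.push({0.0, si + sj * h});
  const double SQ2 = std::sqrt(2.0);
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int p = nd.second, i = p % h, j = p / h;
    if (nd.first > dist(i, j)) continue;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= h || jj < 0 || jj >= w || !mask(ii, jj)) continue;
        double nd2 = nd.first + ((di && dj) ? SQ2 : 1.0);
        if (ISNA(dist(ii, jj)) || nd2 < dist(ii, jj)) {
          dist(ii, jj) = nd2;
          pq.push({nd2, ii + jj * h});
        }
      }
  }
  return dist;
}
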