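#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Label connected components of a 3-D logical array.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Returns an integer vector (column-major, same length as `mask`) with
// 0 = background and components numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> off;
  int maxabs = connectivity == 6 ? 1 : (connectivity == 18 ? 2 : 3);
  std::vector<std::array<int,3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s > 0 && s <= maxabs) nbr.push_back({dx, dy, dz});
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / ((R_xlen_t)nx * ny);
      for (const auto &d : nbr) {
        int x = cx + d[0], y = cy + d[1], z = cz + d[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t j = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// Size of the largest connected component (fast path for Monte-Carlo
// null iterations; avoids allocating a labels vector per iteration).
// [[Rcpp::export]]
int max_component_size_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  int maxabs = connectivity == 6 ? 1 : (connectivity == 18 ? 2 : 3);
  std::vector<std::array<int,3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s > 0 && s <= maxabs) nbr.push_back({dx, dy, dz});
      }
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> stack;
  int best = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || seen[i]) continue;
    int size = 0;
    seen[i] = 1;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / ((R_xlen_t)nx * ny);
      for (const auto &d : nbr) {
        int x = cx + d[0], y = cy + d[1], z = cz + d[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t j = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (mask[j] && !seen[j]) {
          seen[j] = 1;
          stack.push_back(j);
        }
      }
    }
    if (size > best) best = size;
  }
  return best;
}

// Column medians of a numeric matrix (midpoint convention for even n).
// [[Rcpp::export]]
NumericVector col_medians_cpp(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    int h = nr / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (nr % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
      m = 0.5 * (m + buf[h - 1]);
    }
    out[j] = m;
  }
  return out;
}
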