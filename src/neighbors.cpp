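// [[Rcpp::depends(RcppArmadillo)]]
#include "grid.h"
#include <queue>
#include <algorithm>
#include <functional>

using namespace Rcpp;

// Mean distance of each point to its k nearest neighbours (excluding itself).
// Used by the statistical outlier removal filter.
// [[Rcpp::export(name = ".cppMeanKnnDist")]]
NumericVector cpp_mean_knn_dist(const arma::mat& coords, int k) {
  const int n = coords.n_rows;
  if (n <= k) stop("need more points than k");
  // start from a cell size that should hold ~k neighbours and grow on
  // demand; the diagonal-based floor keeps the cell sane for degenerate
  // (planar or collinear) extents where the box volume vanishes
  arma::rowvec lo = arma::min(coords, 0), hi = arma::max(coords, 0);
  double ex = hi(0) - lo(0), ey = hi(1) - lo(1), ez = hi(2) - lo(2);
  double vol = ex * ey * ez;
  double diag = std::sqrt(ex * ex + ey * ey + ez * ez);
  double r0 = vol > 0 ? std::cbrt(vol * (k + 1) / std::max(n, 1)) : 0.0;
  r0 = std::max(r0, 0.5 * diag / std::cbrt((double)std::max(n, 2)));
  if (!(r0 > 0)) r0 = 1e-3;
  HashGrid grid(coords, r0);
  NumericVector out(n);
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) {
    double c[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    double r = r0;
    grid.query(c, r, idx);
    while ((int)idx.size() < k + 1) {  // itself counts once
      r *= 1.6;
      grid.query(c, r, idx);
    }
    std::vector<double> d2;
    d2.reserve(idx.size());
    for (int j : idx) {
      if (j == i) continue;
      double dx = coords(j, 0) - c[0], dy = coords(j, 1) - c[1], dz = coords(j, 2) - c[2];
      d2.push_back(dx * dx + dy * dy + dz * dz);
    }
    // the ring search guarantees >= k candidates but they may not be the
    // true k nearest if the radius cut some off; grow until the kth distance
    // is covered by the search radius
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    double dk = std::sqrt(d2[k - 1]);
    while (dk > r) {
      r = dk * 1.05;
      grid.query(c, r, idx);
      d2.clear();
      for (int j : idx) {
        if (j == i) continue;
        double dx = coords(j, 0) - c[0], dy = coords(j, 1) - c[1], dz = coords(j, 2) - c[2];
        d2.push_back(dx * dx + dy * dy + dz * dz);
      }
      std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
      dk = std::sqrt(d2[k - 1]);
    }
    std::partial_sort(d2.begin(), d2.begin() + k, d2.end());
    double s = 0;
    for (int j = 0; j < k; ++j) s += std::sqrt(d2[j]);
    out[i] = s / k;
  }
  return out;
}

// All pairs (i, j), i < j, with ||p_i - p_j|| <= radius. 1-based.
// [[Rcpp::export(name = ".cppRadiusEdges")]]
IntegerMatrix cpp_radius_edges(const arma::mat& coords, double radius) {
  const int n = coords.n_rows;
  HashGrid grid(coords, radius);
  std::vector<int> from, to, idx;
  for (int i = 0; i < n; ++i) {
    double c[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    grid.query(c, radius, idx);
    for (int j : idx)
      if (j > i) { from.push_back(i + 1); to.push_back(j + 1); }
  }
  IntegerMatrix out(from.size(), 2);
  for (size_t e = 0; e < from.size(); ++e) { out(e, 0) = from[e]; out(e, 1) = to[e]; }
  return out;
}

// Greedy minimum-distance subsampling: keep a point iff no previously kept
// point lies within d_min. Returns logical keep vector (input order).
// [[Rcpp::export(name = ".cppSubsampleMinDist")]]
LogicalVector cpp_subsample_min_dist(const arma::mat& coords, double d_min) {
  const int n = coords.n_rows;
  HashGrid grid(coords, d_min);
  std::vector<int> kept(n, 0), idx;
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double c[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    grid.query(c, d_min, idx, kept.data());
    bool ok = true;
    for (int j : idx) if (j != i) { ok = false; break; }
    out[i] = ok;
    if (ok) kept[i] = 1;
  }
  return out;
}

// Single-linkage connected components at hop distance <= d. Component ids
// 1..K in order of first appearance.
// [[Rcpp::export(name = ".cppConnectedComponents")]]
IntegerVector cpp_connected_components(const arma::mat& coords, double d) {
  const int n = coords.n_rows;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  HashGrid grid(coords, d);
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) {
    double c[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    grid.query(c, d, idx);
    int ri = find(i);
    for (int j : idx) {
      if (j <= i) continue;
      int rj = find(j);
      if (ri != rj) { parent[rj] = ri; ri = find(i); }
    }
  }
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}

// Persistent grid index for repeated radius queries (findBerries hot loop).
// [[Rcpp::export(name = ".cppGridBuild")]]
SEXP cpp_grid_build(const arma::mat& coords, double cell) {
  XPtr<HashGrid> ptr(new HashGrid(coords, cell), true);
  return ptr;
}

// [[Rcpp::export(name = ".cppGridQuery")]]
IntegerVector cpp_grid_query(SEXP grid, NumericVector center, double radius,
                             Nullable<IntegerVector> mask = R_NilValue) {
  XPtr<HashGrid> g(grid);
  std::vector<int> idx;
  const int* m = nullptr;
  IntegerVector mv;
  if (mask.isNotNull()) { mv = mask.get(); m = INTEGER(mv); }
  double c[3] = {center[0], center[1], center[2]};
  g->query(c, radius, idx, m);
  IntegerVector out(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out[i] = idx[i] + 1;
  return out;
}
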