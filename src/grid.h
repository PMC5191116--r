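#ifndef VINECLOUD_GRID_H
#define VINECLOUD_GRID_H

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

// Uniform hash grid over 3-D points. Cell size is fixed at build time but
// queries of arbitrary radius are supported by scanning ceil(r/cell) rings.
class HashGrid {
public:
  arma::mat pts;   // N x 3
  double cell;
  std::unordered_map<int64_t, std::vector<int>> cells;

  HashGrid(const arma::mat& coords, double cell_size) : pts(coords), cell(cell_size) {
    const int n = pts.n_rows;
    cells.reserve(n * 2);
    for (int i = 0; i < n; ++i) {
      cells[key(pts(i, 0), pts(i, 1), pts(i, 2))].push_back(i);
    }
  }

  inline int64_t key(double x, double y, double z) const {
    // 21 bits per axis, offset to keep indices positive
    int64_t ix = (int64_t)std::floor(x / cell) + (1 << 20);
    int64_t iy = (int64_t)std::floor(y / cell) + (1 << 20);
    int64_t iz = (int64_t)std::floor(z / cell) + (1 << 20);
    return (ix << 42) | (iy << 21) | iz;
  }

  // indices (0-based) of points within r of c; optional mask: include only
  // points with mask[i] != 0 (mask may be empty = no mask)
  void query(const double* c, double r, std::vector<int>& out,
             const int* mask = nullptr) const {
    out.clear();
    const double r2 = r * r;
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = (int)std::floor((c[d] - r) / cell);
      hi[d] = (int)std::floor((c[d] + r) / cell);
    }
    for (int ix = lo[0]; ix <= hi[0]; ++ix)
      for (int iy = lo[1]; iy <= hi[1]; ++iy)
        for (int iz = lo[2]; iz <= hi[2]; ++iz) {
          int64_t k = (((int64_t)ix + (1 << 20)) << 42) |
                      (((int64_t)iy + (1 << 20)) << 21) |
                      ((int64_t)iz + (1 << 20));
          auto it = cells.find(k);
          if (it == cells.end()) continue;
          for (int i : it->second) {
            if (mask && !mask[i]) continue;
            double dx = pts(i, 0) - c[0];
            double dy = pts(i, 1) - c[1];
            double dz = pts(i, 2) - c[2];
            if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(i);
          }
        }
  }
};

#endif
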