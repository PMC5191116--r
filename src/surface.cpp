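// [[Rcpp::depends(RcppArmadillo)]]
#include "grid.h"

using namespace Rcpp;

// Per-point unit normals from PCA of the radius neighbourhood, oriented
// towards the nearest camera position. Points with < 3 neighbours (incl.
// themselves) are flagged invalid and get NaN normals.
// [[Rcpp::export(name = ".cppEstimateNormals")]]
List cpp_estimate_normals(const arma::mat& coords, double r_n, const arma::mat& cams) {
  const int n = coords.n_rows;
  HashGrid grid(coords, r_n);
  arma::mat normals(n, 3);
  normals.fill(arma::datum::nan);
  LogicalVector valid(n);
  std::vector<int> idx;
  arma::vec eigval(3);
  arma::mat eigvec(3, 3), cov(3, 3);
  for (int i = 0; i < n; ++i) {
    double c[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    grid.query(c, r_n, idx);
    if ((int)idx.size() < 3) { valid[i] = false; continue; }
    arma::vec mu(3, arma::fill::zeros);
    for (int j : idx) mu += coords.row(j).t();
    mu /= (double)idx.size();
    cov.zeros();
    for (int j : idx) {
      arma::vec d = coords.row(j).t() - mu;
      cov += d * d.t();
    }
    if (!arma::eig_sym(eigval, eigvec, cov)) { valid[i] = false; continue; }
    arma::vec nv = eigvec.col(0);  // smallest eigenvalue
    // orient towards the nearest camera
    int best = 0;
    double bd = arma::datum::inf;
    for (arma::uword m = 0; m < cams.n_rows; ++m) {
      double dx = cams(m, 0) - c[0], dy = cams(m, 1) - c[1], dz = cams(m, 2) - c[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < bd) { bd = d2; best = m; }
    }
    arma::vec tocam = cams.row(best).t() - coords.row(i).t();
    if (arma::dot(nv, tocam) < 0) nv = -nv;
    normals.row(i) = (nv / arma::norm(nv)).t();
    valid[i] = true;
  }
  return List::create(_["normals"] = normals, _["valid"] = valid);
}

// Surface feature histograms: for each point, the joint 5x5x5 histogram of
// the three Darboux-frame angle features over all unordered pairs of
// valid-normal points within r_h (the neighbourhood includes the point).
// Feature ranges: f1 = v.n_t in [-1,1], f2 = u.d_hat in [-1,1],
// f3 = atan2(w.n_t, u.n_t) in [-pi,pi]; equal-width bins, top edge closed.
// [[Rcpp::export(name = ".cppComputeSfh")]]
List cpp_compute_sfh(const arma::mat& coords, const arma::mat& normals,
                     const LogicalVector& valid, double r_h) {
  const int n = coords.n_rows;
  HashGrid grid(coords, r_h);
  arma::mat hist(n, 125, arma::fill::zeros);
  LogicalVector out_valid(n);
  std::vector<int> nb, idx;
  std::vector<int> vmask(n);
  for (int i = 0; i < n; ++i) vmask[i] = valid[i] ? 1 : 0;
  const double pi = arma::datum::pi;
  for (int i = 0; i < n; ++i) {
    if (!valid[i]) { out_valid[i] = false; continue; }
    double c[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    grid.query(c, r_h, idx, vmask.data());
    nb = idx;
    if ((int)nb.size() < 3) { out_valid[i] = false; continue; }  // < 2 neighbours
    arma::rowvec acc(125, arma::fill::zeros);
    const int m = nb.size();
    for (int a = 0; a < m; ++a) {
      const int ia = nb[a];
      const double pax = coords(ia, 0), pay = coords(ia, 1), paz = coords(ia, 2);
      const double nax = normals(ia, 0), nay = normals(ia, 1), naz = normals(ia, 2);
      for (int b = a + 1; b < m; ++b) {
        const int ib = nb[b];
        double dx = coords(ib, 0) - pax, dy = coords(ib, 1) - pay, dz = coords(ib, 2) - paz;
        double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dn < 1e-12) continue;
        double ux, uy, uz, ntx, nty, ntz, ddx = dx / dn, ddy = dy / dn, ddz = dz / dn;
        // source = point whose normal subtends the smaller angle with the
        // vector connecting it to the other point
        double c1 = nax * ddx + nay * ddy + naz * ddz;
        double c2 = -(normals(ib, 0) * ddx + normals(ib, 1) * ddy + normals(ib, 2) * ddz);
        if (c1 >= c2) {
          ux = nax; uy = nay; uz = naz;
          ntx = normals(ib, 0); nty = normals(ib, 1); ntz = normals(ib, 2);
        } else {
          ux = normals(ib, 0); uy = normals(ib, 1); uz = normals(ib, 2);
          ntx = nax; nty = nay; ntz = naz;
          ddx = -ddx; ddy = -ddy; ddz = -ddz;
        }
        // v = d_hat x u (normalised), w = u x v
        double vx = ddy * uz - ddz * uy, vy = ddz * ux - ddx * uz, vz = ddx * uy - ddy * ux;
        double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (vn < 1e-12) { vx = 0; vy = 0; vz = 0; }
        else { vx /= vn; vy /= vn; vz /= vn; }
        double wx = uy * vz - uz * vy, wy = uz * vx - ux * vz, wz = ux * vy - uy * vx;
        double f1 = vx * ntx + vy * nty + vz * ntz;                  // [-1, 1]
        double f2 = ux * ddx + uy * ddy + uz * ddz;                  // [-1, 1]
        double f3 = std::atan2(wx * ntx + wy * nty + wz * ntz,
                               ux * ntx + uy * nty + uz * ntz);      // [-pi, pi]
        int b1 = (int)std::floor((f1 + 1.0) / 2.0 * 5.0); if (b1 > 4) b1 = 4; if (b1 < 0) b1 = 0;
        int b2 = (int)std::floor((f2 + 1.0) / 2.0 * 5.0); if (b2 > 4) b2 = 4; if (b2 < 0) b2 = 0;
        int b3 = (int)std::floor((f3 + pi) / (2.0 * pi) * 5.0); if (b3 > 4) b3 = 4; if (b3 < 0) b3 = 0;
        acc(b1 * 25 + b2 * 5 + b3) += 1.0;
      }
    }
    double tot = arma::accu(acc);
    if (tot > 0) hist.row(i) = acc / tot;
    out_valid[i] = true;
  }
  return List::create(_["sfh"] = hist, _["valid"] = out_valid);
}

// Moving-least-squares smoothing: weighted local plane + bivariate polynomial
// height field; each point is replaced by its projection onto the fitted
// surface. Gaussian weights of scale radius/2. Points with too few
// neighbours pass through unmoved.
// [[Rcpp::export(name = ".cppMlsSmooth")]]
arma::mat cpp_mls_smooth(const arma::mat& coords, double radius, int order) {
  const int n = coords.n_rows;
  const int ncoef = (order + 1) * (order + 2) / 2;
  const int need = std::max(6, ncoef);
  HashGrid grid(coords, radius);
  arma::mat out = coords;
  std::vector<int> idx;
  const double h = radius / 2.0;
  arma::vec eigval(3);
  arma::mat eigvec(3, 3);
  for (int i = 0; i < n; ++i) {
    double c[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    grid.query(c, radius, idx);
    const int m = idx.size();
    if (m < need) continue;
    arma::vec w(m);
    arma::mat P(m, 3);
    for (int a = 0; a < m; ++a) {
      P.row(a) = coords.row(idx[a]);
      double dx = P(a, 0) - c[0], dy = P(a, 1) - c[1], dz = P(a, 2) - c[2];
      w(a) = std::exp(-(dx * dx + dy * dy + dz * dz) / (h * h));
    }
    double wsum = arma::accu(w);
    arma::rowvec mu = (w.t() * P) / wsum;
    arma::mat Q = P.each_row() - mu;
    arma::mat cov = Q.t() * (Q.each_col() % w);
    if (!arma::eig_sym(eigval, eigvec, cov)) continue;
    arma::vec nrm = eigvec.col(0);
    arma::vec u = eigvec.col(2), v = eigvec.col(1);
    // local coordinates
    arma::vec s = Q * u, t = Q * v, z = Q * nrm;
    // design matrix for bivariate polynomial of total degree <= order
    arma::mat A(m, ncoef);
    for (int a = 0; a < m; ++a) {
      int col = 0;
      for (int dtot = 0; dtot <= order; ++dtot)
        for (int ds = dtot; ds >= 0; --ds)
          A(a, col++) = std::pow(s(a), ds) * std::pow(t(a), dtot - ds);
    }
    arma::mat Aw = A.each_col() % w;
    arma::mat AtA = A.t() * Aw;
    arma::vec Atz = A.t() * (w % z);
    arma::vec coef;
    if (!arma::solve(coef, AtA, Atz, arma::solve_opts::no_approx)) continue;
    // evaluate at the source point's in-plane coordinates
    arma::vec d0 = coords.row(i).t() - mu.t();
    double s0 = arma::dot(d0, u), t0 = arma::dot(d0, v);
    double z0 = 0;
    int col = 0;
    for (int dtot = 0; dtot <= order; ++dtot)
      for (int ds = dtot; ds >= 0; --ds)
        z0 += coef(col++) * std::pow(s0, ds) * std::pow(t0, dtot - ds);
    arma::vec np = mu.t() + s0 * u + t0 * v + z0 * nrm;
    out.row(i) = np.t();
  }
  return out;
}
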