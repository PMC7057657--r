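// Fixed-radius neighbour search on 3D point sets via a uniform cell hash
// (cell edge = search radius, 27-cell scan). Contract is exact strict-radius
// search: ||x_i - x_j|| < r, never approximate.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

inline int64_t cell_key(int cx, int cy, int cz) {
  // pack three 21-bit signed cell coordinates into one 64-bit key
  const int64_t OFF = 1 << 20;
  return ((int64_t)(cx + OFF) << 42) | ((int64_t)(cy + OFF) << 21) |
         (int64_t)(cz + OFF);
}

struct CellIndex {
  std::unordered_map<int64_t, std::vector<int>> cells;
  double inv_r;
  const double *x, *y, *z;
  int n;

  CellIndex(const NumericMatrix &coords, double r) {
    n = coords.nrow();
    x = &coords(0, 0);
    y = &coords(0, 1);
    z = &coords(0, 2);
    inv_r = 1.0 / r;
    cells.reserve(n);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(x[i] * inv_r);
      int cy = (int)std::floor(y[i] * inv_r);
      int cz = (int)std::floor(z[i] * inv_r);
      cells[cell_key(cx, cy, cz)].push_back(i);
    }
  }

  // neighbours of point i with distance < r (strict), including i itself
  void query(int i, double r2, std::vector<int> &out) const {
    out.clear();
    int cx = (int)std::floor(x[i] * inv_r);
    int cy = (int)std::floor(y[i] * inv_r);
    int cz = (int)std::floor(z[i] * inv_r);
    for (int ax = cx - 1; ax <= cx + 1; ++ax)
      for (int ay = cy - 1; ay <= cy + 1; ++ay)
        for (int az = cz - 1; az <= cz + 1; ++az) {
          auto it = cells.find(cell_key(ax, ay, az));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
            if (dx * dx + dy * dy + dz * dz < r2) out.push_back(j);
          }
        }
  }
};

} // namespace

// Undirected deduplicated edge list (i < j, 1-based) of all pairs closer
// than r (strict inequality).
// [[Rcpp::export]]
IntegerMatrix cpp_radius_pairs(NumericMatrix coords, double r) {
  CellIndex idx(coords, r);
  double r2 = r * r;
  std::vector<int> nb;
  std::vector<int> ei, ej;
  for (int i = 0; i < idx.n; ++i) {
    idx.query(i, r2, nb);
    for (int j : nb)
      if (j > i) {
        ei.push_back(i + 1);
        ej.push_back(j + 1);
      }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}

// Per-point neighbourhood covariance eigenvalues at each radius.
// Covariance is the unbiased sample covariance (|N|-1 denominator) of the
// neighbours within strict radius, the query point included. Eigenvalues are
// returned ascending; tiny negative values from roundoff are clamped to 0.
// Points with fewer than 2 neighbours get (0,0,0).
// Returns a list, one element per radius: list(lambda = n x 3, n_neighbors).
// [[Rcpp::export]]
List cpp_multiscale_eigen(NumericMatrix coords, NumericVector radii) {
  int n = coords.nrow();
  List out(radii.size());
  std::vector<int> nb;
  for (int ri = 0; ri < radii.size(); ++ri) {
    double r = radii[ri], r2 = r * r;
    CellIndex idx(coords, r);
    NumericMatrix lam(n, 3);
    IntegerVector cnt(n);
    arma::mat33 C;
    arma::vec3 ev;
    for (int i = 0; i < n; ++i) {
      idx.query(i, r2, nb);
      int m = (int)nb.size();
      cnt[i] = m;
      if (m < 2) continue;
      double mx = 0, my = 0, mz = 0;
      for (int j : nb) {
        mx += idx.x[j];
        my += idx.y[j];
        mz += idx.z[j];
      }
      mx /= m;
      my /= m;
      mz /= m;
      double sxx = 0, syy = 0, szz = 0, sxy = 0, sxz = 0, syz = 0;
      for (int j : nb) {
        double dx = idx.x[j] - mx, dy = idx.y[j] - my, dz = idx.z[j] - mz;
        sxx += dx * dx;
        syy += dy * dy;
        szz += dz * dz;
        sxy += dx * dy;
        sxz += dx * dz;
        syz += dy * dz;
      }
      double den = m - 1.0;
      C(0, 0) = sxx / den;
      C(1, 1) = syy / den;
      C(2, 2) = szz / den;
      C(0, 1) = C(1, 0) = sxy / den;
      C(0, 2) = C(2, 0) = sxz / den;
      C(1, 2) = C(2, 1) = syz / den;
      arma::eig_sym(ev, C); // ascending
      for (int k = 0; k < 3; ++k) {
        double v = ev(k);
        if (v < 0 && v > -1e-9) v = 0;
        lam(i, k) = v;
      }
    }
    out[ri] = List::create(Named("lambda") = lam, Named("n_neighbors") = cnt);
  }
  return out;
}

// Batch eigenvalues of symmetric 3x3 matrices given as rows
// (a11, a22, a33, a12, a13, a23); returned ascending.
// [[Rcpp::export]]
NumericMatrix cpp_sym3_eigs(NumericMatrix m6) {
  int n = m6.nrow();
  NumericMatrix out(n, 3);
  arma::mat33 A;
  arma::vec3 ev;
  for (int i = 0; i < n; ++i) {
    A(0, 0) = m6(i, 0);
    A(1, 1) = m6(i, 1);
    A(2, 2) = m6(i, 2);
    A(0, 1) = A(1, 0) = m6(i, 3);
    A(0, 2) = A(2, 0) = m6(i, 4);
    A(1, 2) = A(2, 1) = m6(i, 5);
    arma::eig_sym(ev, A);
    out(i, 0) = ev(0);
    out(i, 1) = ev(1);
    out(i, 2) = ev(2);
  }
  return out;
}
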