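#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// 64-bit key for a 3D grid bin (21 bits per axis, offset to stay positive)
static inline uint64_t bin_key(int ix, int iy, int iz) {
  const uint64_t off = 1 << 20;
  return ((uint64_t)(ix + off) << 42) | ((uint64_t)(iy + off) << 21) |
         (uint64_t)(iz + off);
}

// All unordered pairs with centre distance < cutoff, via a uniform spatial
// grid of bin size = cutoff. Equivalent (as a set) to the all-pairs scan.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  std::unordered_map<uint64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  std::vector<int> bx(n), by(n), bz(n);
  for (int i = 0; i < n; ++i) {
    bx[i] = (int)std::floor(pos(i, 0) / cutoff);
    by[i] = (int)std::floor(pos(i, 1) / cutoff);
    bz[i] = (int)std::floor(pos(i, 2) / cutoff);
    grid[bin_key(bx[i], by[i], bz[i])].push_back(i);
  }
  const double c2 = cutoff * cutoff;
  std::vector<int> out_i, out_j;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(bin_key(bx[i] + dx, by[i] + dy, bz[i] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double ddx = pos(i, 0) - pos(j, 0);
            double ddy = pos(i, 1) - pos(j, 1);
            double ddz = pos(i, 2) - pos(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
              out_i.push_back(i + 1);
              out_j.push_back(j + 1);
            }
          }
        }
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    out(k, 0) = out_i[k];
    out(k, 1) = out_j[k];
  }
  return out;
}

// Deterministic pseudo-random unit vector from an (unordered) id pair, used
// to separate coincident centres reproducibly.
static inline void id_pair_dir(int a, int b, double *v) {
  if (a > b) std::swap(a, b);
  double s1 = std::sin(a * 12.9898 + b * 78.233) * 43758.5453;
  double s2 = std::sin(a * 39.3468 + b * 11.135) * 24634.6345;
  double u1 = s1 - std::floor(s1);
  double u2 = s2 - std::floor(s2);
  double z = 2.0 * u1 - 1.0;
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  double th = 2.0 * M_PI * u2;
  v[0] = r * std::cos(th);
  v[1] = r * std::sin(th);
  v[2] = z;
}

// Linear overlap-spring forces for a precomputed pair list (1-based indices).
// Force on i is k * overlap along the unit vector from j to i; the force on j
// is the exact negation (momentum-free).
// [[Rcpp::export]]
NumericMatrix cpp_repulsion_forces(NumericMatrix pos, NumericVector radius,
                                   IntegerVector pi, IntegerVector pj,
                                   double k, IntegerVector ids) {
  const int n = pos.nrow();
  NumericMatrix f(n, 3);
  for (int p = 0; p < pi.size(); ++p) {
    int i = pi[p] - 1, j = pj[p] - 1;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double sum_r = radius[i] + radius[j];
    double u[3];
    if (d < 1e-12) {
      id_pair_dir(ids[i], ids[j], u);
      d = 0.0;
    } else {
      u[0] = dx / d; u[1] = dy / d; u[2] = dz / d;
    }
    double delta = sum_r - d;
    if (delta <= 0.0) continue;
    double fm = k * delta;
    f(i, 0) += fm * u[0]; f(i, 1) += fm * u[1]; f(i, 2) += fm * u[2];
    f(j, 0) -= fm * u[0]; f(j, 1) -= fm * u[1]; f(j, 2) -= fm * u[2];
  }
  return f;
}

// Compressed volume fractions. For each overlapping neighbour the spherical
// cap cut from the cell by the radical plane is removed:
//   a_i = (d^2 + Ri^2 - Rj^2) / (2 d),  h_i = Ri - a_i,
//   cap = pi h^2 (3 R - h) / 3   for 0 < h <= 2R.
// The result is clamped below at `floor_frac` of the rest volume.
// [[Rcpp::export]]
NumericVector cpp_compressed_fractions(NumericMatrix pos, NumericVector radius,
                                       IntegerVector pi, IntegerVector pj,
                                       double floor_frac) {
  const int n = pos.nrow();
  NumericVector capsum(n);
  for (int p = 0; p < pi.size(); ++p) {
    int i = pi[p] - 1, j = pj[p] - 1;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double Ri = radius[i], Rj = radius[j];
    if (d >= Ri + Rj) continue;
    if (d < 1e-9) { // coincident: treat both as maximally compressed
      capsum[i] += 4.0 * M_PI * Ri * Ri * Ri / 3.0;
      capsum[j] += 4.0 * M_PI * Rj * Rj * Rj / 3.0;
      continue;
    }
    double ai = (d * d + Ri * Ri - Rj * Rj) / (2.0 * d);
    double hi = std::min(2.0 * Ri, Ri - ai);
    if (hi > 0.0) capsum[i] += M_PI * hi * hi * (3.0 * Ri - hi) / 3.0;
    double aj = (d * d + Rj * Rj - Ri * Ri) / (2.0 * d);
    double hj = std::min(2.0 * Rj, Rj - aj);
    if (hj > 0.0) capsum[j] += M_PI * hj * hj * (3.0 * Rj - hj) / 3.0;
  }
  NumericVector frac(n);
  for (int i = 0; i < n; ++i) {
    double rest = 4.0 * M_PI * radius[i] * radius[i] * radius[i] / 3.0;
    double v = rest - capsum[i];
    if (v < floor_frac * rest) v = floor_frac * rest;
    frac[i] = v / rest;
  }
  return frac;
}

// Radius-aware contact pairs: all unordered pairs with centre distance
// < r_i + r_j + skin. Cells with radius <= split_radius are binned on a grid
// sized to their largest diameter; larger cells (few, e.g. growing oocytes)
// are matched by ranged grid queries and a direct large-large scan. Output
// is equivalent to filtering the all-pairs scan by per-pair contact range.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, NumericVector radius,
                                double split_radius, double skin) {
  const int n = pos.nrow();
  std::vector<int> small_idx, big_idx;
  double r_small_max = 0.0;
  for (int i = 0; i < n; ++i) {
    if (radius[i] <= split_radius) {
      small_idx.push_back(i);
      if (radius[i] > r_small_max) r_small_max = radius[i];
    } else {
      big_idx.push_back(i);
    }
  }
  double bin = 2.0 * r_small_max + skin;
  if (bin <= 0) bin = 1.0;
  std::unordered_map<uint64_t, std::vector<int>> grid;
  grid.reserve(small_idx.size() * 2 + 1);
  for (int i : small_idx)
    grid[bin_key((int)std::floor(pos(i, 0) / bin),
                 (int)std::floor(pos(i, 1) / bin),
                 (int)std::floor(pos(i, 2) / bin))].push_back(i);
  std::vector<int> out_i, out_j;
  auto check = [&](int i, int j) {
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double lim = radius[i] + radius[j] + skin;
    if (dx * dx + dy * dy + dz * dz < lim * lim) {
      out_i.push_back(std::min(i, j) + 1);
      out_j.push_back(std::max(i, j) + 1);
    }
  };
  // small-small via the grid
  for (int i : small_idx) {
    int bx = (int)std::floor(pos(i, 0) / bin);
    int by = (int)std::floor(pos(i, 1) / bin);
    int bz = (int)std::floor(pos(i, 2) / bin);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(bin_key(bx + dx, by + dy, bz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second)
            if (j > i) check(i, j);
        }
  }
  // big-small via ranged grid queries
  for (int b : big_idx) {
    double reach = radius[b] + r_small_max + skin;
    int span = (int)std::ceil(reach / bin);
    int bx = (int)std::floor(pos(b, 0) / bin);
    int by = (int)std::floor(pos(b, 1) / bin);
    int bz = (int)std::floor(pos(b, 2) / bin);
    for (int dx = -span; dx <= span; ++dx)
      for (int dy = -span; dy <= span; ++dy)
        for (int dz = -span; dz <= span; ++dz) {
          auto it = grid.find(bin_key(bx + dx, by + dy, bz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) check(b, j);
        }
  }
  // big-big directly
  for (size_t a = 0; a < big_idx.size(); ++a)
    for (size_t c = a + 1; c < big_idx.size(); ++c)
      check(big_idx[a], big_idx[c]);
  IntegerMatrix out(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    out(k, 0) = out_i[k];
    out(k, 1) = out_j[k];
  }
  return out;
}
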