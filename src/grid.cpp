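// Geometric resampling and voxel-set primitives shared by the volume,
// refine, metrics and phantom layers. Grids are stored column-major
// (axis 0 fastest) as in R arrays; a voxel's world position is its center:
// world = origin + index * spacing along the canonical axes.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t lin3(int i, int j, int k, const int* d) {
  return (R_xlen_t)i + (R_xlen_t)d[0] * ((R_xlen_t)j + (R_xlen_t)d[1] * k);
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector values, IntegerVector in_dim,
                           NumericVector in_spacing, NumericVector in_origin,
                           IntegerVector out_dim, NumericVector out_spacing,
                           NumericVector out_origin, bool nearest, double fill) {
  const int di[3] = {in_dim[0], in_dim[1], in_dim[2]};
  const int od[3] = {out_dim[0], out_dim[1], out_dim[2]};
  NumericVector out((R_xlen_t)od[0] * od[1] * od[2]);
  const double* v = values.begin();
  double* o = out.begin();
  // precompute continuous input coordinates per output index, per axis
  std::vector<std::vector<double>> u(3);
  for (int a = 0; a < 3; ++a) {
    u[a].resize(od[a]);
    for (int t = 0; t < od[a]; ++t)
      u[a][t] = (out_origin[a] + t * out_spacing[a] - in_origin[a]) / in_spacing[a];
  }
  R_xlen_t n = 0;
  for (int k = 0; k < od[2]; ++k) {
    for (int j = 0; j < od[1]; ++j) {
      for (int i = 0; i < od[0]; ++i, ++n) {
        double x = u[0][i], y = u[1][j], z = u[2][k];
        if (nearest) {
          int ii = (int)std::lround(x), jj = (int)std::lround(y), kk = (int)std::lround(z);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= di[0] || jj >= di[1] || kk >= di[2])
            o[n] = fill;
          else
            o[n] = v[lin3(ii, jj, kk, di)];
        } else {
          if (x < 0.0 || y < 0.0 || z < 0.0 ||
              x > di[0] - 1.0 || y > di[1] - 1.0 || z > di[2] - 1.0) {
            o[n] = fill;
            continue;
          }
          int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
          int i1 = std::min(i0 + 1, di[0] - 1);
          int j1 = std::min(j0 + 1, di[1] - 1);
          int k1 = std::min(k0 + 1, di[2] - 1);
          double fx = x - i0, fy = y - j0, fz = z - k0;
          double c00 = v[lin3(i0, j0, k0, di)] * (1 - fx) + v[lin3(i1, j0, k0, di)] * fx;
          double c10 = v[lin3(i0, j1, k0, di)] * (1 - fx) + v[lin3(i1, j1, k0, di)] * fx;
          double c01 = v[lin3(i0, j0, k1, di)] * (1 - fx) + v[lin3(i1, j0, k1, di)] * fx;
          double c11 = v[lin3(i0, j1, k1, di)] * (1 - fx) + v[lin3(i1, j1, k1, di)] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          o[n] = c0 * (1 - fz) + c1 * fz;
        }
      }
    }
  }
  return out;
}

// neighbor offsets for 6- (faces) or 26- (all) connectivity
static void neighbor_offsets(int connectivity, std::vector<std::array<int, 3>>& offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
}

// Connected-component labels, components numbered 1..K in order of their
// smallest linear voxel index (deterministic tie-break for keep_largest).
// [[Rcpp::export]]
IntegerVector cpp_cc_label(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(N, 0);
  std::vector<std::array<int, 3>> offs;
  neighbor_offsets(connectivity, offs);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int ci = cur % d[0];
      int cj = (cur / d[0]) % d[1];
      int ck = cur / ((R_xlen_t)d[0] * d[1]);
      for (auto& o : offs) {
        int ni = ci + o[0], nj = cj + o[1], nk = ck + o[2];
        if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2]) continue;
        R_xlen_t nn = lin3(ni, nj, nk, d);
        if (mask[nn] && !lab[nn]) {
          lab[nn] = next;
          stack.push_back(nn);
        }
      }
    }
  }
  return lab;
}

// Iterative region growing: starting from `seed`, repeatedly add voxels of
// `eligible` connected to the current set, for at most max_iter rounds
// (one round = one connectivity shell). Seed voxels are returned as-is.
// [[Rcpp::export]]
IntegerVector cpp_grow(IntegerVector seed, IntegerVector eligible, IntegerVector dim,
                       int connectivity, int max_iter) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector out(N);
  std::vector<std::array<int, 3>> offs;
  neighbor_offsets(connectivity, offs);
  std::vector<R_xlen_t> frontier, nxt;
  for (R_xlen_t s = 0; s < N; ++s) {
    out[s] = seed[s] ? 1 : 0;
    if (seed[s]) frontier.push_back(s);
  }
  for (int it = 0; it < max_iter && !frontier.empty(); ++it) {
    nxt.clear();
    for (R_xlen_t cur : frontier) {
      int ci = cur % d[0];
      int cj = (cur / d[0]) % d[1];
      int ck = cur / ((R_xlen_t)d[0] * d[1]);
      for (auto& o : offs) {
        int ni = ci + o[0], nj = cj + o[1], nk = ck + o[2];
        if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2]) continue;
        R_xlen_t nn = lin3(ni, nj, nk, d);
        if (!out[nn] && eligible[nn]) {
          out[nn] = 1;
          nxt.push_back(nn);
        }
      }
    }
    frontier.swap(nxt);
  }
  return out;
}

// Morphological dilation/erosion with a face (6) or full (26) neighborhood,
// iterated. Out-of-grid voxels count as background for erosion.
// [[Rcpp::export]]
IntegerVector cpp_dilate(IntegerVector mask, IntegerVector dim, int iters, int connectivity) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector cur = clone(mask);
  std::vector<std::array<int, 3>> offs;
  neighbor_offsets(connectivity, offs);
  for (int it = 0; it < iters; ++it) {
    IntegerVector nxt = clone(cur);
    R_xlen_t n = 0;
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i, ++n) {
          if (cur[n]) continue;
          for (auto& o : offs) {
            int ni = i + o[0], nj = j + o[1], nk = k + o[2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2]) continue;
            if (cur[lin3(ni, nj, nk, d)]) {
              nxt[n] = 1;
              break;
            }
          }
        }
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export]]
IntegerVector cpp_erode(IntegerVector mask, IntegerVector dim, int iters, int connectivity) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  IntegerVector cur = clone(mask);
  std::vector<std::array<int, 3>> offs;
  neighbor_offsets(connectivity, offs);
  for (int it = 0; it < iters; ++it) {
    IntegerVector nxt = clone(cur);
    R_xlen_t n = 0;
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i, ++n) {
          if (!cur[n]) continue;
          for (auto& o : offs) {
            int ni = i + o[0], nj = j + o[1], nk = k + o[2];
            bool outside = ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2];
            if (outside || !cur[lin3(ni, nj, nk, d)]) {
              nxt[n] = 0;
              break;
            }
          }
        }
    cur = nxt;
  }
  return cur;
}

// Boundary voxels: mask voxels with at least one face neighbor outside the
// mask (the grid border counts as outside).
// [[Rcpp::export]]
IntegerVector cpp_boundary(IntegerVector mask, IntegerVector dim) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector out(N, 0);
  std::vector<std::array<int, 3>> offs;
  neighbor_offsets(6, offs);
  R_xlen_t n = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i, ++n) {
        if (!mask[n]) continue;
        for (auto& o : offs) {
          int ni = i + o[0], nj = j + o[1], nk = k + o[2];
          bool outside = ni < 0 || nj < 0 || nk < 0 || ni >= d[0] || nj >= d[1] || nk >= d[2];
          if (outside || !mask[lin3(ni, nj, nk, d)]) {
            out[n] = 1;
            break;
          }
        }
      }
  return out;
}

// For each point (row) of A, the minimum Euclidean distance to any row of B.
// Points are in world mm. Brute force; callers keep point sets at surface
// scale (thousands), where this is faster than building search structures.
// [[Rcpp::export]]
NumericVector cpp_min_dists(const arma::mat& A, const arma::mat& B) {
  const arma::uword n = A.n_rows, m = B.n_rows;
  NumericVector out(n);
  for (arma::uword i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (arma::uword j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Union of spheres of radius radius_mm stamped at the given world-mm points
// (rows of pts); used to rasterize tubes along parametric curves.
// [[Rcpp::export]]
LogicalVector cpp_stamp_spheres(IntegerVector dim, NumericVector spacing,
                                NumericVector origin, const arma::mat& pts,
                                double radius_mm) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t N = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector out(N, false);
  const double r2 = radius_mm * radius_mm;
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    double cx = pts(p, 0), cy = pts(p, 1), cz = pts(p, 2);
    int lo[3], hi[3];
    double c[3] = {cx, cy, cz};
    bool empty = false;
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::max(0, (int)std::ceil((c[a] - radius_mm - origin[a]) / spacing[a]));
      hi[a] = std::min(d[a] - 1, (int)std::floor((c[a] + radius_mm - origin[a]) / spacing[a]));
      if (lo[a] > hi[a]) empty = true;
    }
    if (empty) continue;
    for (int k = lo[2]; k <= hi[2]; ++k) {
      double dz = origin[2] + k * spacing[2] - cz;
      for (int j = lo[1]; j <= hi[1]; ++j) {
        double dy = origin[1] + j * spacing[1] - cy;
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double dx = origin[0] + i * spacing[0] - cx;
          if (dx * dx + dy * dy + dz * dz <= r2) out[lin3(i, j, k, d)] = true;
        }
      }
    }
  }
  return out;
}
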