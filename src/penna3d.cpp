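// Low-level voxel kernels: separable convolution with reflective boundaries,
// per-voxel symmetric 3x3 eigenanalysis, nearest-filled hole filling,
// 26-neighbourhood counting, 6-connected erosion and trilinear sampling.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// reflect index into [0, n) (scipy-style "reflect": d c b a | a b c d | d c b a)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// Convolve a 3D array with a 1D kernel along dimension `dim` (1, 2 or 3).
// Kernel is applied as correlation with its centre at floor(K/2); for the
// symmetric/antisymmetric Gaussian-derivative kernels used here the
// distinction from convolution only flips odd-order signs, which the caller
// accounts for by passing kernels already sampled on +offsets.
// [[Rcpp::export]]
arma::cube cpp_conv_dim(const arma::cube& a, const arma::vec& k, const int dim) {
  const int n1 = a.n_rows, n2 = a.n_cols, n3 = a.n_slices;
  const int K = k.n_elem, h = K / 2;
  arma::cube out(n1, n2, n3);
  if (dim == 1) {
    for (int s = 0; s < n3; ++s)
      for (int c = 0; c < n2; ++c)
        for (int r = 0; r < n1; ++r) {
          double acc = 0.0;
          for (int t = 0; t < K; ++t)
            acc += k[t] * a(reflect_idx(r + t - h, n1), c, s);
          out(r, c, s) = acc;
        }
  } else if (dim == 2) {
    for (int s = 0; s < n3; ++s)
      for (int c = 0; c < n2; ++c)
        for (int t = 0; t < K; ++t) {
          const int cc = reflect_idx(c + t - h, n2);
          const double kt = k[t];
          if (t == 0)
            for (int r = 0; r < n1; ++r) out(r, c, s) = kt * a(r, cc, s);
          else
            for (int r = 0; r < n1; ++r) out(r, c, s) += kt * a(r, cc, s);
        }
  } else {
    for (int s = 0; s < n3; ++s)
      for (int t = 0; t < K; ++t) {
        const int ss = reflect_idx(s + t - h, n3);
        const double kt = k[t];
        if (t == 0)
          for (int c = 0; c < n2; ++c)
            for (int r = 0; r < n1; ++r) out(r, c, s) = kt * a(r, c, ss);
        else
          for (int c = 0; c < n2; ++c)
            for (int r = 0; r < n1; ++r) out(r, c, s) += kt * a(r, c, ss);
      }
  }
  return out;
}

// Per-voxel eigen-decomposition of the symmetric Hessian. For each voxel
// where mask is true, returns the unit eigenvector of the smallest
// (by magnitude when smallest_magnitude, else signed) eigenvalue.
// Voxels whose two smallest-|eigenvalue| candidates are closer than
// degen_tol * max|lambda| are flagged degenerate (still populated).
// [[Rcpp::export]]
List cpp_eig3_field(const arma::cube& hxx, const arma::cube& hxy,
                    const arma::cube& hxz, const arma::cube& hyy,
                    const arma::cube& hyz, const arma::cube& hzz,
                    const LogicalVector& mask, const bool smallest_magnitude,
                    const double degen_tol) {
  const int n1 = hxx.n_rows, n2 = hxx.n_cols, n3 = hxx.n_slices;
  const int N = n1 * n2 * n3;
  NumericVector vx(N, NA_REAL), vy(N, NA_REAL), vz(N, NA_REAL);
  LogicalVector degen(N, FALSE);
  arma::mat33 H;
  arma::vec3 ev;
  arma::mat33 evec;
  for (int i = 0; i < N; ++i) {
    if (!mask[i]) continue;
    H(0, 0) = hxx[i]; H(0, 1) = hxy[i]; H(0, 2) = hxz[i];
    H(1, 0) = hxy[i]; H(1, 1) = hyy[i]; H(1, 2) = hyz[i];
    H(2, 0) = hxz[i]; H(2, 1) = hyz[i]; H(2, 2) = hzz[i];
    arma::eig_sym(ev, evec, H); // ascending eigenvalues
    int sel = 0;
    if (smallest_magnitude) {
      double best = std::abs(ev[0]);
      for (int j = 1; j < 3; ++j)
        if (std::abs(ev[j]) < best) { best = std::abs(ev[j]); sel = j; }
      double second = arma::datum::inf;
      for (int j = 0; j < 3; ++j)
        if (j != sel && std::abs(ev[j]) < second) second = std::abs(ev[j]);
      const double amax = std::max({std::abs(ev[0]), std::abs(ev[1]),
                                    std::abs(ev[2])});
      if (amax <= 0 || (second - std::abs(ev[sel])) <= degen_tol * amax)
        degen[i] = TRUE;
    } else {
      sel = 0; // eig_sym ascending: signed smallest first
      const double amax = std::max({std::abs(ev[0]), std::abs(ev[1]),
                                    std::abs(ev[2])});
      if (amax <= 0 || (ev[1] - ev[0]) <= degen_tol * amax) degen[i] = TRUE;
    }
    vx[i] = evec(0, sel); vy[i] = evec(1, sel); vz[i] = evec(2, sel);
  }
  return List::create(_["vx"] = vx, _["vy"] = vy, _["vz"] = vz,
                      _["degenerate"] = degen);
}

// Fill empty voxels from their nearest filled voxel (grid-geodesic
// approximation: `radius` rounds of 26-neighbour relaxation on a chamfer
// distance, each empty voxel copying the value reached by the shortest
// accumulated physical path). Voxels farther than `radius` steps remain
// unfilled.
// [[Rcpp::export]]
List cpp_nn_fill(const arma::cube& values, const LogicalVector& filled,
                 const int radius, const arma::vec& spacing) {
  const int n1 = values.n_rows, n2 = values.n_cols, n3 = values.n_slices;
  const int N = n1 * n2 * n3;
  arma::cube val = values;
  arma::cube dist(n1, n2, n3);
  LogicalVector out_filled(N);
  for (int i = 0; i < N; ++i) {
    out_filled[i] = filled[i];
    dist[i] = filled[i] ? 0.0 : arma::datum::inf;
  }
  for (int it = 0; it < radius; ++it) {
    bool changed = false;
    arma::cube nd = dist;
    arma::cube nv = val;
    for (int s = 0; s < n3; ++s)
      for (int c = 0; c < n2; ++c)
        for (int r = 0; r < n1; ++r) {
          const int i = r + n1 * (c + n2 * s);
          if (filled[i]) continue;
          double bd = dist(r, c, s), bv = val(r, c, s);
          for (int ds = -1; ds <= 1; ++ds)
            for (int dc = -1; dc <= 1; ++dc)
              for (int dr = -1; dr <= 1; ++dr) {
                if (!dr && !dc && !ds) continue;
                const int rr = r + dr, cc = c + dc, ss = s + ds;
                if (rr < 0 || rr >= n1 || cc < 0 || cc >= n2 ||
                    ss < 0 || ss >= n3) continue;
                if (!std::isfinite(dist(rr, cc, ss))) continue;
                const double step = std::sqrt(
                    dr * dr * spacing[0] * spacing[0] +
                    dc * dc * spacing[1] * spacing[1] +
                    ds * ds * spacing[2] * spacing[2]);
                const double cand = dist(rr, cc, ss) + step;
                if (cand < bd) { bd = cand; bv = val(rr, cc, ss); }
              }
          if (bd < dist(r, c, s)) {
            nd(r, c, s) = bd; nv(r, c, s) = bv; changed = true;
          }
        }
    dist = nd; val = nv;
    if (!changed) break;
  }
  for (int i = 0; i < N; ++i)
    if (!filled[i] && std::isfinite(dist[i])) out_filled[i] = TRUE;
  return List::create(_["values"] = val, _["filled"] = out_filled);
}

// Count non-missing 26-neighbours of every voxel of a logical support grid.
// [[Rcpp::export]]
IntegerVector cpp_count_neighbors26(const LogicalVector& support,
                                    const IntegerVector& dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector out(n1 * n2 * n3, 0);
  for (int s = 0; s < n3; ++s)
    for (int c = 0; c < n2; ++c)
      for (int r = 0; r < n1; ++r) {
        int cnt = 0;
        for (int ds = -1; ds <= 1; ++ds)
          for (int dc = -1; dc <= 1; ++dc)
            for (int dr = -1; dr <= 1; ++dr) {
              if (!dr && !dc && !ds) continue;
              const int rr = r + dr, cc = c + dc, ss = s + ds;
              if (rr < 0 || rr >= n1 || cc < 0 || cc >= n2 ||
                  ss < 0 || ss >= n3) continue;
              if (support[rr + n1 * (cc + n2 * ss)]) ++cnt;
            }
        out[r + n1 * (c + n2 * s)] = cnt;
      }
  return out;
}

// Iterated 3D binary erosion with the 6-connected structuring element.
// Out-of-volume voxels count as background, so the border erodes.
// [[Rcpp::export]]
LogicalVector cpp_erode6(const LogicalVector& mask, const IntegerVector& dims,
                         const int iterations) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int N = n1 * n2 * n3;
  std::vector<char> cur(N), nxt(N);
  for (int i = 0; i < N; ++i) cur[i] = mask[i] ? 1 : 0;
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int it = 0; it < iterations; ++it) {
    for (int s = 0; s < n3; ++s)
      for (int c = 0; c < n2; ++c)
        for (int r = 0; r < n1; ++r) {
          const int i = r + n1 * (c + n2 * s);
          char keep = cur[i];
          if (keep) {
            for (int j = 0; j < 6 && keep; ++j) {
              const int rr = r + off[j][0], cc = c + off[j][1],
                        ss = s + off[j][2];
              if (rr < 0 || rr >= n1 || cc < 0 || cc >= n2 ||
                  ss < 0 || ss >= n3) { keep = 0; break; }
              if (!cur[rr + n1 * (cc + n2 * ss)]) keep = 0;
            }
          }
          nxt[i] = keep;
        }
    cur.swap(nxt);
  }
  LogicalVector out(N);
  for (int i = 0; i < N; ++i) out[i] = cur[i] != 0;
  return out;
}

// Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
// Coordinates outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(const arma::cube& a, const arma::mat& coords,
                            const double fill) {
  const int n1 = a.n_rows, n2 = a.n_cols, n3 = a.n_slices;
  const int N = coords.n_rows;
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > n1 - 1 || y > n2 - 1 || z > n3 - 1) {
      out[i] = fill; continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == n1 - 1) --x0; if (y0 == n2 - 1) --y0; if (z0 == n3 - 1) --z0;
    if (n1 == 1) x0 = 0; if (n2 == 1) y0 = 0; if (n3 == 1) z0 = 0;
    const int x1 = std::min(x0 + 1, n1 - 1), y1 = std::min(y0 + 1, n2 - 1),
              z1 = std::min(z0 + 1, n3 - 1);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const double c00 = a(x0, y0, z0) * (1 - fx) + a(x1, y0, z0) * fx;
    const double c10 = a(x0, y1, z0) * (1 - fx) + a(x1, y1, z0) * fx;
    const double c01 = a(x0, y0, z1) * (1 - fx) + a(x1, y0, z1) * fx;
    const double c11 = a(x0, y1, z1) * (1 - fx) + a(x1, y1, z1) * fx;
    out[i] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}

// Nearest-neighbour sampling (for masks) at continuous 0-based coordinates.
// [[Rcpp::export]]
NumericVector cpp_nearest(const arma::cube& a, const arma::mat& coords,
                          const double fill) {
  const int n1 = a.n_rows, n2 = a.n_cols, n3 = a.n_slices;
  const int N = coords.n_rows;
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    const long r = std::lround(coords(i, 0)), c = std::lround(coords(i, 1)),
               s = std::lround(coords(i, 2));
    out[i] = (r < 0 || r >= n1 || c < 0 || c >= n2 || s < 0 || s >= n3)
                 ? fill : a(r, c, s);
  }
  return out;
}
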