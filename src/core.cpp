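#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Array convention throughout: a 3D volume is an R array with dim = (nz, ny, nx),
// so the z index varies fastest in memory. Linear index = iz + nz*(iy + ny*ix).

static inline int reflect_idx(int i, int n) {
  // symmetric (half-sample) reflection: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export(name = ".conv3d_axis")]]
NumericVector conv3d_axis(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector dim = vol.attr("dim");
  if (dim.size() != 3) stop("volume must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  int kh = kl / 2;
  NumericVector out(vol.size());
  out.attr("dim") = dim;
  int n[3] = {nz, ny, nx};
  int stride[3] = {1, nz, nz * ny};
  int na = n[axis], sa = stride[axis];
  // iterate over all lines along `axis`
  int b1 = (axis == 0) ? 1 : 0;
  int b2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[b2]; ++j2) {
    for (int j1 = 0; j1 < n[b1]; ++j1) {
      int base = j1 * stride[b1] + j2 * stride[b2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int k = 0; k < kl; ++k) {
          int src = reflect_idx(i + k - kh, na);
          acc += kernel[k] * vol[base + src * sa];
        }
        out[base + i * sa] = acc;
      }
    }
  }
  return out;
}

// Strict 26-neighbourhood local maxima with deterministic plateau handling:
// a voxel is a maximum if it is >= every in-volume neighbour and strictly
// greater than every neighbour with a smaller linear index (so on a flat
// plateau only the lexicographically smallest voxel qualifies).
// [[Rcpp::export(name = ".local_maxima_3d")]]
IntegerVector local_maxima_3d(NumericVector vol, double threshold) {
  IntegerVector dim = vol.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        int idx = iz + nz * (iy + ny * ix);
        double v = vol[idx];
        if (ISNAN(v)) stop("NaN voxel encountered");
        if (v <= threshold) continue;
        bool ok = true;
        for (int dx = -1; dx <= 1 && ok; ++dx)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dz = -1; dz <= 1 && ok; ++dz) {
              if (!dx && !dy && !dz) continue;
              int jx = ix + dx, jy = iy + dy, jz = iz + dz;
              if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
                continue;
              int jdx = jz + nz * (jy + ny * jx);
              double w = vol[jdx];
              if (ISNAN(w)) stop("NaN voxel encountered");
              if (w > v || (w == v && jdx < idx)) ok = false;
            }
        if (ok) hits.push_back(idx + 1); // 1-based for R
      }
  return wrap(hits);
}

// 26-connected component labelling of a logical mask (3D). Labels are
// assigned in increasing order of the component's smallest linear index,
// which makes the labelling deterministic.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx]) continue;
    ++next;
    stack.clear();
    stack.push_back(idx);
    lab[idx] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cz = cur % nz, cy = (cur / nz) % ny, cx = cur / (nz * ny);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int jx = cx + dx, jy = cy + dy, jz = cz + dz;
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
              continue;
            int j = jz + nz * (jy + ny * jx);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing w, applied in place along one axis of the volume.
static void dt1d(std::vector<double> &f, double w, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb) {
  int n = f.size();
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INFINITY) continue;
    double s;
    while (true) {
      if (f[v[k]] == INFINITY) { // empty parabola so far
        if (k == 0) { v[k] = q; zb[k] = -INFINITY; zb[k+1] = INFINITY; break; }
        --k;
        continue;
      }
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; continue; }
      ++k;
      v[k] = q;
      zb[k] = s;
      zb[k + 1] = INFINITY;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    if (f[v[k]] == INFINITY) d[q] = INFINITY;
    else {
      double dq = w * (q - v[k]);
      d[q] = dq * dq + f[v[k]];
    }
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact anisotropic Euclidean distance transform: distance (in physical
// units) from every voxel to the nearest TRUE voxel of `mask`.
// voxel_size is (z, y, x).
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, NumericVector voxel_size) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  std::vector<double> f(n);
  for (int i = 0; i < n; ++i) f[i] = mask[i] ? 0.0 : INFINITY;
  int dims[3] = {nz, ny, nx};
  int stride[3] = {1, nz, nz * ny};
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> line(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  for (int axis = 0; axis < 3; ++axis) {
    int na = dims[axis], sa = stride[axis];
    double w = voxel_size[axis];
    int b1 = (axis == 0) ? 1 : 0;
    int b2 = (axis == 2) ? 1 : 2;
    line.resize(na);
    d.resize(na);
    v.resize(na);
    zb.resize(na + 1);
    for (int j2 = 0; j2 < dims[b2]; ++j2)
      for (int j1 = 0; j1 < dims[b1]; ++j1) {
        int base = j1 * stride[b1] + j2 * stride[b2];
        bool any = false;
        for (int i = 0; i < na; ++i) {
          line[i] = f[base + i * sa];
          if (line[i] != INFINITY) any = true;
        }
        if (!any) continue;
        dt1d(line, w, d, v, zb);
        for (int i = 0; i < na; ++i) f[base + i * sa] = line[i];
      }
  }
  NumericVector out(n);
  out.attr("dim") = dim;
  for (int i = 0; i < n; ++i)
    out[i] = (f[i] == INFINITY) ? NA_REAL : std::sqrt(f[i]);
  return out;
}

// Square linear assignment problem, shortest augmenting path (O(n^3)).
// Returns, for each row, the assigned column (1-based). Deterministic.
// [[Rcpp::export(name = ".solve_lap")]]
IntegerVector solve_lap(NumericMatrix a) {
  int n = a.nrow(), m = a.ncol();
  if (n > m) stop("cost matrix needs nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), vpot(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= m; ++j)
        if (!used[j]) {
          double cur = a(i0 - 1, j - 1) - u[i0] - vpot[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      if (!std::isfinite(delta)) stop("infeasible assignment problem");
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; vpot[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
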