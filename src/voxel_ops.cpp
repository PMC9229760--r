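#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbor offsets for 6/18/26 connectivity.
static std::vector<std::array<int, 3>> conn_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Label connected components of a 3-D logical array (x fastest).
// Labels are assigned in raster order of each component's first voxel,
// i.e. component 1 has the lowest (z, y, x) first voxel.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim,
                           int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> off = conn_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int qx = x + off[k][0], qy = y + off[k][1], qz = z + off[k][2];
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
          continue;
        R_xlen_t q = qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
        if (mask[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Binary dilation with an explicit structuring-element offset list (n x 3).
// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int m = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
    for (int k = 0; k < m; ++k) {
      int qx = x + offsets(k, 0), qy = y + offsets(k, 1), qz = z + offsets(k, 2);
      if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
        continue;
      out[qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz)] = true;
    }
  }
  return out;
}

// Binary erosion.  Out-of-grid neighbors count as foreground, the adjoint
// convention for grid-clipped dilation: with it, erode/dilate form an
// adjunction and open/close compositions are idempotent filters.
// [[Rcpp::export(name = ".erode_cpp")]]
LogicalVector erode_cpp(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int m = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
    bool keep = true;
    for (int k = 0; k < m && keep; ++k) {
      int qx = x + offsets(k, 0), qy = y + offsets(k, 1), qz = z + offsets(k, 2);
      if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
        continue;
      if (!mask[qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz)])
        keep = false;
    }
    out[i] = keep;
  }
  return out;
}

// Felzenszwalb & Huttenlocher 1-D squared distance transform.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else
        break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact 2-D squared Euclidean distance (in pixels) to the nearest site pixel.
// [[Rcpp::export(name = ".edt2d_cpp")]]
NumericVector edt2d_cpp(LogicalVector sites, int nx, int ny) {
  const double BIG = 1e20;
  NumericVector out((R_xlen_t)nx * ny);
  std::vector<double> f(std::max(nx, ny)), d(std::max(nx, ny));
  // pass along x
  std::vector<double> tmp((size_t)nx * ny);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = sites[x + (R_xlen_t)nx * y] ? 0.0 : BIG;
    dt1d(f, d, nx);
    for (int x = 0; x < nx; ++x) tmp[(size_t)x + (size_t)nx * y] = d[x];
  }
  // pass along y
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = tmp[(size_t)x + (size_t)nx * y];
    dt1d(f, d, ny);
    for (int y = 0; y < ny; ++y) out[x + (R_xlen_t)nx * y] = d[y];
  }
  return out;
}
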