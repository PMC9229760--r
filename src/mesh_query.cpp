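#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Closest point on triangle (a, b, c) to p (Ericson, Real-Time Collision
// Detection) and the squared distance.
static double pt_tri_sq(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto sq = [&](const double *q) {
    double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0 && d2 <= 0) return sq(a);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) return sq(b);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    double q[3] = {a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]};
    return sq(q);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) return sq(c);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    double q[3] = {a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]};
    return sq(q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                   b[2] + w * (c[2] - b[2])};
    return sq(q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = {a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
                 a[2] + ab[2] * v + ac[2] * w};
  return sq(q);
}

struct TriGrid {
  int n[3];
  double lo[3], h[3];
  std::vector<std::vector<int>> cells;
  int cell_of(int ix, int iy, int iz) const {
    return ix + n[0] * (iy + n[1] * iz);
  }
  int clampi(double c, int ax) const {
    int i = (int)std::floor((c - lo[ax]) / h[ax]);
    return std::min(std::max(i, 0), n[ax] - 1);
  }
};

static TriGrid build_grid(const NumericMatrix &V, const IntegerMatrix &F) {
  TriGrid g;
  const int nf = F.nrow();
  double hi[3];
  for (int a = 0; a < 3; ++a) {
    g.lo[a] = R_PosInf;
    hi[a] = R_NegInf;
  }
  for (int i = 0; i < V.nrow(); ++i)
    for (int a = 0; a < 3; ++a) {
      g.lo[a] = std::min(g.lo[a], V(i, a));
      hi[a] = std::max(hi[a], V(i, a));
    }
  int target = std::max(1, (int)std::cbrt((double)nf));
  for (int a = 0; a < 3; ++a) {
    double ext = std::max(hi[a] - g.lo[a], 1e-9);
    g.n[a] = std::min(std::max(target, 1), 128);
    g.h[a] = ext / g.n[a] * (1 + 1e-12);
    g.lo[a] -= 1e-9;
  }
  g.cells.resize((size_t)g.n[0] * g.n[1] * g.n[2]);
  for (int f = 0; f < nf; ++f) {
    int i0[3], i1[3];
    for (int a = 0; a < 3; ++a) {
      double mn = std::min({V(F(f, 0) - 1, a), V(F(f, 1) - 1, a), V(F(f, 2) - 1, a)});
      double mx = std::max({V(F(f, 0) - 1, a), V(F(f, 1) - 1, a), V(F(f, 2) - 1, a)});
      i0[a] = g.clampi(mn, a);
      i1[a] = g.clampi(mx, a);
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          g.cells[g.cell_of(ix, iy, iz)].push_back(f);
  }
  return g;
}

// Exact unsigned distance from each query point to the closest point on any
// triangle of the mesh, via an expanding-ring search on a uniform grid.
// [[Rcpp::export(name = ".closest_tri_dist_cpp")]]
NumericVector closest_tri_dist_cpp(NumericMatrix P, NumericMatrix V,
                                   IntegerMatrix F) {
  TriGrid g = build_grid(V, F);
  const int np = P.nrow(), nf = F.nrow();
  std::vector<double> tflat(9 * (size_t)nf);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c)
      for (int a = 0; a < 3; ++a)
        tflat[9 * (size_t)f + 3 * c + a] = V(F(f, c) - 1, a);
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    int c0[3];
    for (int a = 0; a < 3; ++a) c0[a] = g.clampi(p[a], a);
    double best = R_PosInf;
    double hmin = std::min({g.h[0], g.h[1], g.h[2]});
    int max_ring = g.n[0] + g.n[1] + g.n[2];
    for (int ring = 0; ring <= max_ring; ++ring) {
      // lower bound on distance to any cell in this ring or beyond
      if (ring > 0 && best < R_PosInf) {
        double lb = (ring - 1) * hmin;
        // conservative: also account for point offset within its own cell
        if (lb * lb > best) break;
      }
      bool any_cell = false;
      for (int iz = c0[2] - ring; iz <= c0[2] + ring; ++iz) {
        if (iz < 0 || iz >= g.n[2]) continue;
        for (int iy = c0[1] - ring; iy <= c0[1] + ring; ++iy) {
          if (iy < 0 || iy >= g.n[1]) continue;
          for (int ix = c0[0] - ring; ix <= c0[0] + ring; ++ix) {
            if (ix < 0 || ix >= g.n[0]) continue;
            int r = std::max({std::abs(ix - c0[0]), std::abs(iy - c0[1]),
                              std::abs(iz - c0[2])});
            if (r != ring) continue;
            any_cell = true;
            const std::vector<int> &tris = g.cells[g.cell_of(ix, iy, iz)];
            for (size_t t = 0; t < tris.size(); ++t) {
              const double *tv = &tflat[9 * (size_t)tris[t]];
              double d = pt_tri_sq(p, tv, tv + 3, tv + 6);
              if (d < best) best = d;
            }
          }
        }
      }
      if (!any_cell && best < R_PosInf) break;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// Voxelize a watertight mesh on a regular grid: voxel center inside iff an
// odd number of surface crossings lie above it along +z.  One ray per (x, y)
// column classifies the whole column.  Centers are nudged sub-micron in x/y
// so rays avoid triangle edges exactly.
// [[Rcpp::export(name = ".voxelize_cpp")]]
LogicalVector voxelize_cpp(NumericMatrix V, IntegerMatrix F,
                           NumericVector lo, double pitch, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nf = F.nrow();
  const double jx = 1.2345e-7, jy = 2.3456e-7;
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  // flat copies (matrix accessors are too slow in the inner loop)
  std::vector<double> tx(3 * nf), ty(3 * nf), tz(3 * nf);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) {
      tx[3 * f + c] = V(F(f, c) - 1, 0);
      ty[3 * f + c] = V(F(f, c) - 1, 1);
      tz[3 * f + c] = V(F(f, c) - 1, 2);
    }
  // bin triangles into the (x, y) columns their bbox overlaps
  std::vector<std::vector<int>> cols((size_t)nx * ny);
  auto clampi = [](int i, int n) { return std::min(std::max(i, 0), n - 1); };
  for (int f = 0; f < nf; ++f) {
    double mnx = std::min({tx[3 * f], tx[3 * f + 1], tx[3 * f + 2]});
    double mxx = std::max({tx[3 * f], tx[3 * f + 1], tx[3 * f + 2]});
    double mny = std::min({ty[3 * f], ty[3 * f + 1], ty[3 * f + 2]});
    double mxy = std::max({ty[3 * f], ty[3 * f + 1], ty[3 * f + 2]});
    int i0 = clampi((int)std::floor((mnx - lo[0]) / pitch), nx);
    int i1 = clampi((int)std::ceil((mxx - lo[0]) / pitch), nx);
    int j0 = clampi((int)std::floor((mny - lo[1]) / pitch), ny);
    int j1 = clampi((int)std::ceil((mxy - lo[1]) / pitch), ny);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        cols[(size_t)i + (size_t)nx * j].push_back(f);
  }
  std::vector<double> zc;
  for (int iy = 0; iy < ny; ++iy) {
    double py = lo[1] + iy * pitch + jy;
    for (int ix = 0; ix < nx; ++ix) {
      const std::vector<int> &tris = cols[(size_t)ix + (size_t)nx * iy];
      if (tris.empty()) continue;
      double px = lo[0] + ix * pitch + jx;
      zc.clear();
      for (size_t t = 0; t < tris.size(); ++t) {
        int f = tris[t];
        double x1 = tx[3 * f], y1 = ty[3 * f], z1 = tz[3 * f];
        double x2 = tx[3 * f + 1], y2 = ty[3 * f + 1], z2 = tz[3 * f + 1];
        double x3 = tx[3 * f + 2], y3 = ty[3 * f + 2], z3 = tz[3 * f + 2];
        double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
        if (det == 0) continue;
        double u = ((px - x1) * (y3 - y1) - (py - y1) * (x3 - x1)) / det;
        double v = ((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        zc.push_back(z1 + u * (z2 - z1) + v * (z3 - z1));
      }
      if (zc.empty()) continue;
      std::sort(zc.begin(), zc.end());
      // voxel center z in (zc[k-1], zc[k]] is inside iff (n - k) is odd
      size_t k = 0;
      for (int iz = 0; iz < nz; ++iz) {
        double pz = lo[2] + iz * pitch;
        while (k < zc.size() && zc[k] <= pz) ++k;
        if ((zc.size() - k) % 2 == 1)
          out[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = true;
      }
    }
  }
  return out;
}

// Parity (ray-casting) inside test: casts a +z ray from each point.  Query
// coordinates are nudged by a fixed sub-micron offset so rays avoid vertices
// and edges exactly; the induced error shell is far below any voxel pitch.
// [[Rcpp::export(name = ".points_in_mesh_cpp")]]
LogicalVector points_in_mesh_cpp(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F) {
  const int nf = F.nrow(), np = P.nrow();
  const double jx = 1.2345e-7, jy = 2.3456e-7;
  // 2-D bins over (x, y)
  double lo[2] = {R_PosInf, R_PosInf}, hi[2] = {R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i)
    for (int a = 0; a < 2; ++a) {
      lo[a] = std::min(lo[a], V(i, a));
      hi[a] = std::max(hi[a], V(i, a));
    }
  int nb = std::max(1, std::min(256, (int)std::sqrt((double)nf)));
  double hx = std::max(hi[0] - lo[0], 1e-9) / nb * (1 + 1e-12);
  double hy = std::max(hi[1] - lo[1], 1e-9) / nb * (1 + 1e-12);
  std::vector<std::vector<int>> bins((size_t)nb * nb);
  auto bx = [&](double x) {
    return std::min(std::max((int)std::floor((x - lo[0]) / hx), 0), nb - 1);
  };
  auto by = [&](double y) {
    return std::min(std::max((int)std::floor((y - lo[1]) / hy), 0), nb - 1);
  };
  for (int f = 0; f < nf; ++f) {
    double mnx = std::min({V(F(f, 0) - 1, 0), V(F(f, 1) - 1, 0), V(F(f, 2) - 1, 0)});
    double mxx = std::max({V(F(f, 0) - 1, 0), V(F(f, 1) - 1, 0), V(F(f, 2) - 1, 0)});
    double mny = std::min({V(F(f, 0) - 1, 1), V(F(f, 1) - 1, 1), V(F(f, 2) - 1, 1)});
    double mxy = std::max({V(F(f, 0) - 1, 1), V(F(f, 1) - 1, 1), V(F(f, 2) - 1, 1)});
    for (int iy = by(mny); iy <= by(mxy); ++iy)
      for (int ix = bx(mnx); ix <= bx(mxx); ++ix)
        bins[(size_t)ix + (size_t)nb * iy].push_back(f);
  }
  LogicalVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    double px = P(ip, 0) + jx, py = P(ip, 1) + jy, pz = P(ip, 2);
    if (px < lo[0] || px > hi[0] || py < lo[1] || py > hi[1]) {
      out[ip] = false;
      continue;
    }
    int crossings = 0;
    const std::vector<int> &tris = bins[(size_t)bx(px) + (size_t)nb * by(py)];
    for (size_t t = 0; t < tris.size(); ++t) {
      int f = tris[t];
      double x1 = V(F(f, 0) - 1, 0), y1 = V(F(f, 0) - 1, 1), z1 = V(F(f, 0) - 1, 2);
      double x2 = V(F(f, 1) - 1, 0), y2 = V(F(f, 1) - 1, 1), z2 = V(F(f, 1) - 1, 2);
      double x3 = V(F(f, 2) - 1, 0), y3 = V(F(f, 2) - 1, 1), z3 = V(F(f, 2) - 1, 2);
      double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
      if (det == 0) continue;
      double u = ((px - x1) * (y3 - y1) - (py - y1) * (x3 - x1)) / det;
      double v = ((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) / det;
      if (u < 0 || v < 0 || u + v > 1) continue;
      double zq = z1 + u * (z2 - z1) + v * (z3 - z1);
      if (zq > pz) ++crossings;
    }
    out[ip] = (crossings % 2) == 1;
  }
  return out;
}
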