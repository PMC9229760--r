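#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Iso-surface extraction on a conforming tetrahedral decomposition of the
// voxel lattice (Freudenthal 6-tet split of each cell, all cells sharing the
// same main diagonal so face diagonals match between neighbors).  Every
// surface vertex lies on a unique lattice edge and is keyed by its node-id
// pair, so shared vertices are exact and the output is watertight for any
// field whose iso-crossings stay away from the grid boundary (callers pad
// binary masks by one background layer).

struct Key {
  uint64_t k;
  bool operator==(const Key &o) const { return k == o.k; }
};
struct KeyHash {
  size_t operator()(const Key &key) const {
    return std::hash<uint64_t>()(key.k);
  }
};

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(NumericVector vol, IntegerVector dim, double iso,
                    NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // the 6 permutations of axis insertion order: tet = path c0 -> c7
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::unordered_map<Key, int, KeyHash> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  auto node_index = [&](int x, int y, int z) -> uint64_t {
    return (uint64_t)x + (uint64_t)nx * ((uint64_t)y + (uint64_t)ny * z);
  };
  auto node_pos = [&](uint64_t id, double *p) {
    uint64_t x = id % nx, y = (id / nx) % ny, z = id / ((uint64_t)nx * ny);
    p[0] = ox + sx * x;
    p[1] = oy + sy * y;
    p[2] = oz + sz * z;
  };
  // vertex on lattice edge (a, b) at the iso crossing
  auto edge_vert = [&](uint64_t a, uint64_t b, double va, double vb) -> int {
    if (a > b) {
      std::swap(a, b);
      std::swap(va, vb);
    }
    Key key{a * (uint64_t)nx * ny * nz + b};
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    double pa[3], pb[3];
    node_pos(a, pa);
    node_pos(b, pb);
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, id);
    return id;
  };
  // emit triangle oriented so its normal points from inside toward outside
  auto emit = [&](int a, int b, int c, const double *dir) {
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxn = uy * wz - uz * wy, nyn = uz * wx - ux * wz,
           nzn = ux * wy - uy * wx;
    if (nxn * dir[0] + nyn * dir[1] + nzn * dir[2] < 0) std::swap(b, c);
    f0.push_back(a);
    f1.push_back(b);
    f2.push_back(c);
  };

  uint64_t corner[4];
  double val[4];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        // skip uniform cells quickly
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          double v = vol[node_index(x + (c & 1), y + ((c >> 1) & 1),
                                    z + ((c >> 2) & 1))];
          (v > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          int cx = x, cy = y, cz = z;
          corner[0] = node_index(cx, cy, cz);
          for (int s = 0; s < 3; ++s) {
            int ax = perms[p][s];
            if (ax == 0) ++cx;
            else if (ax == 1) ++cy;
            else ++cz;
            corner[s + 1] = node_index(cx, cy, cz);
          }
          int inside[4], outside[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            val[c] = vol[corner[c]];
            if (val[c] > iso) inside[ni++] = c;
            else outside[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          // direction inside -> outside for orientation
          double pin[3] = {0, 0, 0}, pout[3] = {0, 0, 0}, q[3], dir[3];
          for (int c = 0; c < ni; ++c) {
            node_pos(corner[inside[c]], q);
            for (int d = 0; d < 3; ++d) pin[d] += q[d] / ni;
          }
          for (int c = 0; c < no; ++c) {
            node_pos(corner[outside[c]], q);
            for (int d = 0; d < 3; ++d) pout[d] += q[d] / no;
          }
          for (int d = 0; d < 3; ++d) dir[d] = pout[d] - pin[d];
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? inside[0] : outside[0];
            const int *oth = (ni == 1) ? outside : inside;
            int e0 = edge_vert(corner[apex], corner[oth[0]], val[apex], val[oth[0]]);
            int e1 = edge_vert(corner[apex], corner[oth[1]], val[apex], val[oth[1]]);
            int e2 = edge_vert(corner[apex], corner[oth[2]], val[apex], val[oth[2]]);
            emit(e0, e1, e2, dir);
          } else {
            // two in, two out: quad with corners on the four mixed edges
            int a = inside[0], b = inside[1], c = outside[0], d = outside[1];
            int eac = edge_vert(corner[a], corner[c], val[a], val[c]);
            int ead = edge_vert(corner[a], corner[d], val[a], val[d]);
            int ebc = edge_vert(corner[b], corner[c], val[b], val[c]);
            int ebd = edge_vert(corner[b], corner[d], val[b], val[d]);
            emit(eac, ead, ebd, dir);
            emit(eac, ebd, ebc, dir);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = f0[i] + 1;
    F(i, 1) = f1[i] + 1;
    F(i, 2) = f2[i] + 1;
  }
  return List::create(Named("vertices") = V, Named("faces") = F);
}
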