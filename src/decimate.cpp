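#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Quadric-error edge-collapse decimation (Garland & Heckbert style) with a
// link-condition test so collapses never create non-manifold edges and a
// normal-flip test so surviving faces keep their orientation.

namespace {

struct Cand {
  double cost;
  int a, b;
  long stamp;  // sum of vertex stamps at push time; invalid if stale
  bool operator<(const Cand &o) const { return cost > o.cost; }  // min-heap
};

struct Mesh {
  std::vector<std::array<double, 3>> pos;
  std::vector<std::array<int, 3>> face;
  std::vector<bool> face_alive, vert_alive;
  std::vector<std::vector<int>> vfaces;  // incident alive faces (may hold stale)
  std::vector<std::array<double, 10>> Q;
  std::vector<long> stamp;

  void face_normal(int f, double *n) const {
    const std::array<int, 3> &t = face[f];
    double u[3], v[3];
    for (int i = 0; i < 3; ++i) {
      u[i] = pos[t[1]][i] - pos[t[0]][i];
      v[i] = pos[t[2]][i] - pos[t[0]][i];
    }
    n[0] = u[1] * v[2] - u[2] * v[1];
    n[1] = u[2] * v[0] - u[0] * v[2];
    n[2] = u[0] * v[1] - u[1] * v[0];
  }
  void add_face_quadric(int f) {
    double n[3];
    face_normal(f, n);
    double len = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (len < 1e-30) return;
    for (int i = 0; i < 3; ++i) n[i] /= len;
    const std::array<double, 3> &p = pos[face[f][0]];
    double d = -(n[0] * p[0] + n[1] * p[1] + n[2] * p[2]);
    double v4[4] = {n[0], n[1], n[2], d};
    int k = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i; j < 4; ++j, ++k)
        for (int c = 0; c < 3; ++c) Q[face[f][c]][k] += v4[i] * v4[j];
  }
  static double eval_q(const std::array<double, 10> &q, const double *p) {
    // symmetric 4x4, packed upper triangle row-wise
    double x = p[0], y = p[1], z = p[2];
    return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x +
           q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y + q[7] * z * z +
           2 * q[8] * z + q[9];
  }
};

}  // namespace

// signed volume contribution of triangle (a, b, c): det / 6
static double tri_vol(const std::array<double, 3> &a,
                      const std::array<double, 3> &b,
                      const std::array<double, 3> &c) {
  return (a[0] * (b[1] * c[2] - b[2] * c[1]) -
          a[1] * (b[0] * c[2] - b[2] * c[0]) +
          a[2] * (b[0] * c[1] - b[1] * c[0])) / 6.0;
}

// vol_budget: maximum allowed cumulative |enclosed-volume change| (<= 0
// disables the gate, e.g. for open meshes).  Collapses that would push the
// running volume drift past the budget are refused, so shape-destroying
// collapses on coarse meshes (a 12-face box) are rejected while dense
// meshes decimate freely.
// [[Rcpp::export(name = ".decimate_qem_cpp")]]
List decimate_qem_cpp(NumericMatrix Vm, IntegerMatrix Fm, int target_faces,
                      double vol_budget) {
  Mesh M;
  const int nv = Vm.nrow(), nf = Fm.nrow();
  M.pos.resize(nv);
  for (int i = 0; i < nv; ++i)
    M.pos[i] = {Vm(i, 0), Vm(i, 1), Vm(i, 2)};
  M.face.resize(nf);
  for (int f = 0; f < nf; ++f)
    M.face[f] = {Fm(f, 0) - 1, Fm(f, 1) - 1, Fm(f, 2) - 1};
  M.face_alive.assign(nf, true);
  M.vert_alive.assign(nv, true);
  M.vfaces.resize(nv);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) M.vfaces[M.face[f][c]].push_back(f);
  M.Q.assign(nv, {0, 0, 0, 0, 0, 0, 0, 0, 0, 0});
  for (int f = 0; f < nf; ++f) M.add_face_quadric(f);
  M.stamp.assign(nv, 0);

  std::priority_queue<Cand> heap;
  auto neighbors = [&](int v) {
    std::vector<int> nb;
    for (size_t i = 0; i < M.vfaces[v].size(); ++i) {
      int f = M.vfaces[v][i];
      if (!M.face_alive[f]) continue;
      for (int c = 0; c < 3; ++c)
        if (M.face[f][c] != v) nb.push_back(M.face[f][c]);
    }
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    return nb;
  };
  auto best_point = [&](int a, int b, double *p) {
    std::array<double, 10> q;
    for (int i = 0; i < 10; ++i) q[i] = M.Q[a][i] + M.Q[b][i];
    double cand[3][3] = {
        {(M.pos[a][0] + M.pos[b][0]) / 2, (M.pos[a][1] + M.pos[b][1]) / 2,
         (M.pos[a][2] + M.pos[b][2]) / 2},
        {M.pos[a][0], M.pos[a][1], M.pos[a][2]},
        {M.pos[b][0], M.pos[b][1], M.pos[b][2]}};
    double best = R_PosInf;
    for (int i = 0; i < 3; ++i) {
      double c = Mesh::eval_q(q, cand[i]);
      if (c < best) {
        best = c;
        for (int d = 0; d < 3; ++d) p[d] = cand[i][d];
      }
    }
    return best;
  };
  auto push_edge = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    double p[3];
    double c = best_point(a, b, p);
    heap.push({c, a, b, M.stamp[a] + M.stamp[b]});
  };
  for (int v = 0; v < nv; ++v) {
    std::vector<int> nb = neighbors(v);
    for (size_t i = 0; i < nb.size(); ++i)
      if (nb[i] > v) push_edge(v, nb[i]);
  }

  int faces_alive = nf;
  double vol_drift = 0;
  while (faces_alive > target_faces && !heap.empty()) {
    Cand c = heap.top();
    heap.pop();
    int a = c.a, b = c.b;
    if (!M.vert_alive[a] || !M.vert_alive[b]) continue;
    if (c.stamp != M.stamp[a] + M.stamp[b]) continue;
    // edge faces
    std::vector<int> efaces;
    for (size_t i = 0; i < M.vfaces[a].size(); ++i) {
      int f = M.vfaces[a][i];
      if (!M.face_alive[f]) continue;
      const std::array<int, 3> &t = M.face[f];
      if (t[0] == b || t[1] == b || t[2] == b) efaces.push_back(f);
    }
    if (efaces.size() != 2) continue;  // boundary or non-manifold edge
    if (faces_alive - 2 < target_faces && faces_alive - 2 < 4) break;
    // link condition: exactly the 2 opposite vertices in common
    std::vector<int> na = neighbors(a), nbv = neighbors(b), common;
    std::set_intersection(na.begin(), na.end(), nbv.begin(), nbv.end(),
                          std::back_inserter(common));
    if (common.size() != 2) continue;
    double p[3];
    best_point(a, b, p);
    // flip test on surviving faces incident to a or b
    bool ok = true;
    std::array<double, 3> old_a = M.pos[a], old_b = M.pos[b];
    for (int side = 0; side < 2 && ok; ++side) {
      int v = side == 0 ? a : b;
      for (size_t i = 0; i < M.vfaces[v].size() && ok; ++i) {
        int f = M.vfaces[v][i];
        if (!M.face_alive[f]) continue;
        if (f == efaces[0] || f == efaces[1]) continue;
        double n0[3];
        M.face_normal(f, n0);
        M.pos[v] = {p[0], p[1], p[2]};
        double n1[3];
        M.face_normal(f, n1);
        M.pos[v] = side == 0 ? old_a : old_b;
        if (n0[0] * n1[0] + n0[1] * n1[1] + n0[2] * n1[2] <= 0) ok = false;
      }
    }
    if (!ok) continue;
    // exact enclosed-volume change of this collapse
    double dv = 0;
    if (vol_budget > 0) {
      std::array<double, 3> pnew = {p[0], p[1], p[2]};
      dv -= tri_vol(M.pos[M.face[efaces[0]][0]], M.pos[M.face[efaces[0]][1]],
                    M.pos[M.face[efaces[0]][2]]);
      dv -= tri_vol(M.pos[M.face[efaces[1]][0]], M.pos[M.face[efaces[1]][1]],
                    M.pos[M.face[efaces[1]][2]]);
      for (int side = 0; side < 2; ++side) {
        int v = side == 0 ? a : b;
        for (size_t i = 0; i < M.vfaces[v].size(); ++i) {
          int f = M.vfaces[v][i];
          if (!M.face_alive[f]) continue;
          if (f == efaces[0] || f == efaces[1]) continue;
          std::array<std::array<double, 3>, 3> tri;
          for (int c2 = 0; c2 < 3; ++c2) tri[c2] = M.pos[M.face[f][c2]];
          dv -= tri_vol(tri[0], tri[1], tri[2]);
          for (int c2 = 0; c2 < 3; ++c2)
            if (M.face[f][c2] == v) tri[c2] = pnew;
          dv += tri_vol(tri[0], tri[1], tri[2]);
        }
      }
      if (std::abs(vol_drift + dv) > vol_budget) continue;
    }
    // perform collapse: b merges into a at p
    vol_drift += dv;
    M.pos[a] = {p[0], p[1], p[2]};
    for (int i = 0; i < 10; ++i) M.Q[a][i] += M.Q[b][i];
    M.face_alive[efaces[0]] = false;
    M.face_alive[efaces[1]] = false;
    faces_alive -= 2;
    for (size_t i = 0; i < M.vfaces[b].size(); ++i) {
      int f = M.vfaces[b][i];
      if (!M.face_alive[f]) continue;
      for (int cc = 0; cc < 3; ++cc)
        if (M.face[f][cc] == b) M.face[f][cc] = a;
      M.vfaces[a].push_back(f);
    }
    M.vert_alive[b] = false;
    ++M.stamp[a];
    std::vector<int> nn = neighbors(a);
    for (size_t i = 0; i < nn.size(); ++i) {
      ++M.stamp[nn[i]];
    }
    for (size_t i = 0; i < nn.size(); ++i) push_edge(a, nn[i]);
    // re-seed edges among a's neighbors whose stamps changed
    for (size_t i = 0; i < nn.size(); ++i) {
      std::vector<int> nn2 = neighbors(nn[i]);
      for (size_t j = 0; j < nn2.size(); ++j)
        if (nn2[j] > nn[i]) push_edge(nn[i], nn2[j]);
    }
  }

  // compact
  std::vector<int> vmap(nv, -1);
  int nv2 = 0;
  for (int v = 0; v < nv; ++v)
    if (M.vert_alive[v]) vmap[v] = nv2++;
  int nf2 = 0;
  for (int f = 0; f < nf; ++f)
    if (M.face_alive[f]) ++nf2;
  NumericMatrix V2(nv2, 3);
  IntegerMatrix F2(nf2, 3);
  for (int v = 0; v < nv; ++v)
    if (vmap[v] >= 0)
      for (int d = 0; d < 3; ++d) V2(vmap[v], d) = M.pos[v][d];
  int fi = 0;
  for (int f = 0; f < nf; ++f)
    if (M.face_alive[f]) {
      for (int c = 0; c < 3; ++c) F2(fi, c) = vmap[M.face[f][c]] + 1;
      ++fi;
    }
  return List::create(Named("vertices") = V2, Named("faces") = F2);
}
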