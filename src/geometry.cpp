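#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <map>
#include <random>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Incremental (Bowyer-Watson) 3D Delaunay tetrahedralisation and alpha-complex
// boundary extraction. Input points receive a deterministic, index-hashed
// jitter to break the cospherical degeneracies that voxel-grid point clouds
// are full of; the jitter is orders of magnitude below voxel size so it has
// no geometric consequence.
// ---------------------------------------------------------------------------

struct Tet {
  int v[4];
  double cx, cy, cz, r2;
  bool alive;
};

static bool circumsphere(const std::vector<double> &px,
                         const std::vector<double> &py,
                         const std::vector<double> &pz, int a, int b, int c,
                         int d, double &cx, double &cy, double &cz,
                         double &r2) {
  double ax = px[a], ay = py[a], az = pz[a];
  double m[3][3], rhs[3];
  int idx[3] = {b, c, d};
  for (int r = 0; r < 3; ++r) {
    double dx = px[idx[r]] - ax, dy = py[idx[r]] - ay, dz = pz[idx[r]] - az;
    m[r][0] = 2 * dx;
    m[r][1] = 2 * dy;
    m[r][2] = 2 * dz;
    rhs[r] = dx * dx + dy * dy + dz * dz;
  }
  double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
               m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
               m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  double scale = 0;
  for (int r = 0; r < 3; ++r)
    for (int s = 0; s < 3; ++s) scale = std::max(scale, std::fabs(m[r][s]));
  if (std::fabs(det) < 1e-12 * scale * scale * scale) return false;
  // Cramer
  double x =
      (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
       m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
       m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2])) / det;
  double y =
      (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
       rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
       m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0])) / det;
  double z =
      (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
       m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
       rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0])) / det;
  cx = ax + x;
  cy = ay + y;
  cz = az + z;
  r2 = x * x + y * y + z * z;
  return true;
}

static double orient3d(const std::vector<double> &px,
                       const std::vector<double> &py,
                       const std::vector<double> &pz, int a, int b, int c,
                       int d) {
  double bx = px[b] - px[a], by = py[b] - py[a], bz = pz[b] - pz[a];
  double cx = px[c] - px[a], cy = py[c] - py[a], cz = pz[c] - pz[a];
  double dx = px[d] - px[a], dy = py[d] - py[a], dz = pz[d] - pz[a];
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) +
         bz * (cx * dy - cy * dx);
}

struct FaceKey {
  int a, b, c;
  bool operator<(const FaceKey &o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

static FaceKey make_key(int a, int b, int c) {
  int v[3] = {a, b, c};
  std::sort(v, v + 3);
  return {v[0], v[1], v[2]};
}

// Returns alive non-super tetrahedra (vertex indices + circumradius^2).
static void delaunay_core(std::vector<double> &px, std::vector<double> &py,
                          std::vector<double> &pz, int n,
                          std::vector<Tet> &tets) {
  // deterministic jitter scaled to the cloud extent
  double lo[3] = {px[0], py[0], pz[0]}, hi[3] = {px[0], py[0], pz[0]};
  for (int i = 0; i < n; ++i) {
    lo[0] = std::min(lo[0], px[i]); hi[0] = std::max(hi[0], px[i]);
    lo[1] = std::min(lo[1], py[i]); hi[1] = std::max(hi[1], py[i]);
    lo[2] = std::min(lo[2], pz[i]); hi[2] = std::max(hi[2], pz[i]);
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) diag = 1.0;
  double jit = diag * 1e-7;
  std::mt19937 rng(911u);
  std::uniform_real_distribution<double> U(-1.0, 1.0);
  for (int i = 0; i < n; ++i) {
    px[i] += jit * U(rng);
    py[i] += jit * U(rng);
    pz[i] += jit * U(rng);
  }
  // super-tetrahedron
  double cx = (lo[0] + hi[0]) / 2, cy = (lo[1] + hi[1]) / 2,
         cz = (lo[2] + hi[2]) / 2;
  double R = 50.0 * diag + 1.0;
  px.push_back(cx - 2 * R); py.push_back(cy - R); pz.push_back(cz - R);
  px.push_back(cx + 2 * R); py.push_back(cy - R); pz.push_back(cz - R);
  px.push_back(cx);         py.push_back(cy + 2 * R); pz.push_back(cz - R);
  px.push_back(cx);         py.push_back(cy); pz.push_back(cz + 2 * R);
  Tet t0;
  t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
  circumsphere(px, py, pz, n, n + 1, n + 2, n + 3, t0.cx, t0.cy, t0.cz, t0.r2);
  t0.alive = true;
  tets.clear();
  tets.push_back(t0);
  // shuffled deterministic insertion order
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::mt19937 rng2(4242u);
  for (int i = n - 1; i > 0; --i) {
    int j = rng2() % (i + 1);
    std::swap(ord[i], ord[j]);
  }
  std::vector<int> bad;
  std::map<FaceKey, std::pair<int, std::array<int, 3>>> faces;
  for (int s = 0; s < n; ++s) {
    int p = ord[s];
    bad.clear();
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      double dx = px[p] - tets[t].cx, dy = py[p] - tets[t].cy,
             dz = pz[p] - tets[t].cz;
      if (dx * dx + dy * dy + dz * dz < tets[t].r2) bad.push_back((int)t);
    }
    if (bad.empty()) continue;  // should not happen with jitter; skip safely
    faces.clear();
    for (int t : bad) {
      const int *v = tets[t].v;
      const int fo[4][3] = {{v[1], v[2], v[3]},
                            {v[0], v[2], v[3]},
                            {v[0], v[1], v[3]},
                            {v[0], v[1], v[2]}};
      for (int f = 0; f < 4; ++f) {
        FaceKey k = make_key(fo[f][0], fo[f][1], fo[f][2]);
        auto it = faces.find(k);
        if (it == faces.end())
          faces[k] = {1, {fo[f][0], fo[f][1], fo[f][2]}};
        else
          it->second.first++;
      }
      tets[t].alive = false;
    }
    for (auto &kv : faces) {
      if (kv.second.first != 1) continue;  // internal cavity face
      int a = kv.second.second[0], b = kv.second.second[1],
          c = kv.second.second[2];
      Tet nt;
      nt.v[0] = a; nt.v[1] = b; nt.v[2] = c; nt.v[3] = p;
      if (orient3d(px, py, pz, a, b, c, p) < 0) std::swap(nt.v[1], nt.v[2]);
      if (!circumsphere(px, py, pz, nt.v[0], nt.v[1], nt.v[2], nt.v[3], nt.cx,
                        nt.cy, nt.cz, nt.r2)) {
        // numerically flat sliver: give it an enormous circumsphere so a
        // later insertion destroys it
        nt.cx = px[a]; nt.cy = py[a]; nt.cz = pz[a];
        nt.r2 = 1e30;
      }
      nt.alive = true;
      tets.push_back(nt);
    }
    // periodic compaction keeps the scan cheap
    if (tets.size() > 16384) {
      size_t w = 0;
      for (size_t t = 0; t < tets.size(); ++t)
        if (tets[t].alive) tets[w++] = tets[t];
      tets.resize(w);
    }
  }
}

// Boundary triangles (1-based vertex indices, outward-oriented) of the alpha
// complex {tetrahedra with circumradius <= alpha}.
// [[Rcpp::export]]
List cpp_alpha_surface(NumericMatrix pts, double alpha) {
  int n = pts.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0);
    py[i] = pts(i, 1);
    pz[i] = pts(i, 2);
  }
  std::vector<Tet> tets;
  delaunay_core(px, py, pz, n, tets);
  double a2 = alpha * alpha;
  std::map<FaceKey, std::pair<int, std::array<int, 4>>> faces;
  int kept = 0;
  for (auto &t : tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    if (t.r2 > a2) continue;
    ++kept;
    const int *v = t.v;
    const int fo[4][4] = {{v[1], v[2], v[3], v[0]},
                          {v[0], v[2], v[3], v[1]},
                          {v[0], v[1], v[3], v[2]},
                          {v[0], v[1], v[2], v[3]}};
    for (int f = 0; f < 4; ++f) {
      FaceKey k = make_key(fo[f][0], fo[f][1], fo[f][2]);
      auto it = faces.find(k);
      if (it == faces.end())
        faces[k] = {1, {fo[f][0], fo[f][1], fo[f][2], fo[f][3]}};
      else
        it->second.first++;
    }
  }
  std::vector<std::array<int, 3>> tris;
  for (auto &kv : faces) {
    if (kv.second.first != 1) continue;
    int a = kv.second.second[0], b = kv.second.second[1],
        c = kv.second.second[2], d = kv.second.second[3];
    // orient the face so its normal points away from the opposite vertex d
    double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
    double vx = px[c] - px[a], vy = py[c] - py[a], vz = pz[c] - pz[a];
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz,
           nz = ux * vy - uy * vx;
    double wx = px[d] - px[a], wy = py[d] - py[a], wz = pz[d] - pz[a];
    if (nx * wx + ny * wy + nz * wz > 0) std::swap(b, c);
    tris.push_back({a + 1, b + 1, c + 1});
  }
  IntegerMatrix T((int)tris.size(), 3);
  for (size_t i = 0; i < tris.size(); ++i) {
    T(i, 0) = tris[i][0];
    T(i, 1) = tris[i][1];
    T(i, 2) = tris[i][2];
  }
  return List::create(_["triangles"] = T, _["n_tets"] = kept);
}

// Moller-Trumbore over a whole mesh: farthest non-negative hit per ray.
// [[Rcpp::export]]
List cpp_ray_mesh_farthest(NumericMatrix origins, NumericMatrix dirs,
                           NumericMatrix verts, IntegerMatrix tris) {
  int nr = origins.nrow(), nt = tris.nrow();
  NumericVector tmax(nr, NA_REAL);
  IntegerVector nhits(nr, 0);
  for (int r = 0; r < nr; ++r) {
    double ox = origins(r, 0), oy = origins(r, 1), oz = origins(r, 2);
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best = -1;
    int cnt = 0;
    for (int t = 0; t < nt; ++t) {
      int ia = tris(t, 0) - 1, ib = tris(t, 1) - 1, ic = tris(t, 2) - 1;
      double ax = verts(ia, 0), ay = verts(ia, 1), az = verts(ia, 2);
      double e1x = verts(ib, 0) - ax, e1y = verts(ib, 1) - ay,
             e1z = verts(ib, 2) - az;
      double e2x = verts(ic, 0) - ax, e2y = verts(ic, 1) - ay,
             e2z = verts(ic, 2) - az;
      double hx = dy * e2z - dz * e2y, hy = dz * e2x - dx * e2z,
             hz = dx * e2y - dy * e2x;
      double det = e1x * hx + e1y * hy + e1z * hz;
      if (std::fabs(det) < 1e-12) continue;
      double inv = 1.0 / det;
      double sx = ox - ax, sy = oy - ay, sz = oz - az;
      double u = (sx * hx + sy * hy + sz * hz) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qx = sy * e1z - sz * e1y, qy = sz * e1x - sx * e1z,
             qz = sx * e1y - sy * e1x;
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double tt = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (tt < -1e-9) continue;
      ++cnt;
      if (tt > best) best = tt;
    }
    if (cnt > 0) tmax[r] = best;
    nhits[r] = cnt;
  }
  return List::create(_["t"] = tmax, _["nhits"] = nhits);
}
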