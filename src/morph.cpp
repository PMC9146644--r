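#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double BIG = 1e30;  // finite sentinel for "no source on this line"

// Felzenszwalb & Huttenlocher 1D squared distance transform with sample step h.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) to the nearest TRUE voxel; >= 1e30 if none.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = mask[i] ? 0.0 : BIG;
  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (size_t)j * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (size_t)j * nx] = d[j];
    }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (size_t)k * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + (size_t)k * nx * ny] = d[k];
    }
  return out;
}

// Connected-component labels (0 = background); connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  IntegerVector lab(N, 0);
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (man == 0) continue;
            if (connectivity == 6 && man != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t q = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
            if (mask[q] && !lab[q]) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// Fill interior cavities: background voxels not 6-connected to the array border.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  std::vector<char> vis(N, 0);
  std::vector<size_t> stack;
  for (size_t s = 0; s < N; ++s) {
    int i = s % nx, j = (s / nx) % ny, k = s / ((size_t)nx * ny);
    bool border = (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 ||
                   k == nz - 1);
    if (border && !mask[s] && !vis[s]) {
      vis[s] = 1;
      stack.push_back(s);
    }
  }
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    size_t p = stack.back();
    stack.pop_back();
    int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
    for (int t = 0; t < 6; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      size_t q = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
      if (!mask[q] && !vis[q]) {
        vis[q] = 1;
        stack.push_back(q);
      }
    }
  }
  LogicalVector out(N);
  for (size_t s = 0; s < N; ++s) out[s] = mask[s] || !vis[s];
  return out;
}

// Per-slice (z) 2D hole fill, 4-connectivity.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes2d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((size_t)nx * ny * nz);
  std::vector<char> vis;
  std::vector<int> stack;
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  for (int k = 0; k < nz; ++k) {
    size_t base = (size_t)k * nx * ny;
    vis.assign((size_t)nx * ny, 0);
    stack.clear();
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool border = (i == 0 || j == 0 || i == nx - 1 || j == ny - 1);
        int s = j * nx + i;
        if (border && !mask[base + s]) {
          if (!vis[s]) { vis[s] = 1; stack.push_back(s); }
        }
      }
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int i = p % nx, j = p / nx;
      for (int t = 0; t < 4; ++t) {
        int ii = i + di[t], jj = j + dj[t];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        int q = jj * nx + ii;
        if (!mask[base + q] && !vis[q]) {
          vis[q] = 1;
          stack.push_back(q);
        }
      }
    }
    for (int s = 0; s < nx * ny; ++s) out[base + s] = mask[base + s] || !vis[s];
  }
  return out;
}

// Separable Gaussian smoothing (sigma in voxels per axis), reflected edges.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector data, IntegerVector dim,
                           NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector cur = clone(data);
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (auto &w : ker) w /= sum;
    NumericVector nxt(N);
    int na = n[ax];
    // iterate over all lines along axis ax
    size_t nlines = N / na;
    for (size_t L = 0; L < nlines; ++L) {
      // decompose line index into the two other axes
      size_t rem = L, start = 0;
      for (int b = 0; b < 3; ++b) {
        if (b == ax) continue;
        size_t c = rem % n[b];
        rem /= n[b];
        start += c * stride[b];
      }
      for (int q = 0; q < na; ++q) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int p = q + t;
          if (p < 0) p = -p - 1;
          if (p >= na) p = 2 * na - p - 1;
          acc += ker[t + r] * cur[start + (size_t)p * stride[ax]];
        }
        nxt[start + (size_t)q * stride[ax]] = acc;
      }
    }
    cur = nxt;
  }
  return cur;
}

// Even-odd scanline fill of a closed polygon on an (nx x ny) voxel-center grid.
// [[Rcpp::export]]
LogicalVector cpp_fill_polygon(int nx, int ny, NumericVector px, NumericVector py,
                               double x0, double y0, double dx, double dy) {
  LogicalVector out((size_t)nx * ny, false);
  int m = px.size();
  std::vector<double> xs;
  for (int j = 0; j < ny; ++j) {
    double yc = y0 + j * dy;
    xs.clear();
    for (int e = 0; e < m; ++e) {
      double ya = py[e], yb = py[(e + 1) % m];
      double xa = px[e], xb = px[(e + 1) % m];
      if ((ya <= yc) != (yb <= yc)) {
        xs.push_back(xa + (yc - ya) / (yb - ya) * (xb - xa));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int ia = (int)std::ceil((xs[p] - x0) / dx - 1e-9);
      int ib = (int)std::floor((xs[p + 1] - x0) / dx + 1e-9);
      if (ia < 0) ia = 0;
      if (ib > nx - 1) ib = nx - 1;
      for (int i = ia; i <= ib; ++i) out[(size_t)j * nx + i] = true;
    }
  }
  return out;
}
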