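#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Catmull-Rom cubic kernel (Keys, a = -0.5); reproduces linear fields exactly.
static inline double cubw(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.0 + t * t * (-2.5 + 1.5 * t);
  if (t < 2.0) return 2.0 + t * (-4.0 + t * (2.5 - 0.5 * t));
  return 0.0;
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

static inline double getv(const double *d, int nx, int ny, int nz,
                          int i, int j, int k) {
  i = clampi(i, 0, nx - 1);
  j = clampi(j, 0, ny - 1);
  k = clampi(k, 0, nz - 1);
  return d[(size_t)k * nx * ny + (size_t)j * nx + i];
}

// Sample one point at continuous voxel index (u,v,w); mode 0=nearest,1=linear,2=cubic.
static double sample_one(const double *d, int nx, int ny, int nz,
                         double u, double v, double w, int mode) {
  if (mode == 0) {
    return getv(d, nx, ny, nz, (int)std::llround(u), (int)std::llround(v),
                (int)std::llround(w));
  }
  if (mode == 1) {
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
    double fu = u - i0, fv = v - j0, fw = w - k0;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double wt = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) * (dk ? fw : 1 - fw);
          if (wt != 0.0) acc += wt * getv(d, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
        }
    return acc;
  }
  // cubic
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
  double fu = u - i0, fv = v - j0, fw = w - k0;
  double wx[4], wy[4], wz[4];
  for (int t = -1; t <= 2; ++t) {
    wx[t + 1] = cubw(fu - t);
    wy[t + 1] = cubw(fv - t);
    wz[t + 1] = cubw(fw - t);
  }
  double acc = 0.0;
  for (int dk = -1; dk <= 2; ++dk) {
    double wk = wz[dk + 1];
    if (wk == 0.0) continue;
    for (int dj = -1; dj <= 2; ++dj) {
      double wjk = wy[dj + 1] * wk;
      if (wjk == 0.0) continue;
      for (int di = -1; di <= 2; ++di) {
        double wt = wx[di + 1] * wjk;
        if (wt != 0.0) acc += wt * getv(d, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector data, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, int mode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *d = REAL(data);
  for (int r = 0; r < n; ++r) {
    double u = (pts(r, 0) - origin[0]) / spacing[0];
    double v = (pts(r, 1) - origin[1]) / spacing[1];
    double w = (pts(r, 2) - origin[2]) / spacing[2];
    out[r] = sample_one(d, nx, ny, nz, u, v, w, mode);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample_grid(NumericVector data, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                IntegerVector odim, NumericVector ospacing,
                                NumericVector oorigin, int mode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *d = REAL(data);
  size_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    double w = (oorigin[2] + k * ospacing[2] - origin[2]) / spacing[2];
    for (int j = 0; j < oy; ++j) {
      double v = (oorigin[1] + j * ospacing[1] - origin[1]) / spacing[1];
      for (int i = 0; i < ox; ++i, ++idx) {
        double u = (oorigin[0] + i * ospacing[0] - origin[0]) / spacing[0];
        out[idx] = sample_one(d, nx, ny, nz, u, v, w, mode);
      }
    }
  }
  return out;
}
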