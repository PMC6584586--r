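#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline int reflect_idx(int k, int na) {
  if (k < 0) k = -k;
  if (k >= na) k = 2 * na - 2 - k;
  return k < 0 ? 0 : k;
}

// separable symmetric-kernel convolution of one 3-D component with
// mirror-reflective boundaries; result lands back in `a`
static void gauss3_raw(double *a, double *tmp, int nx, int ny, int nz,
                       const double *wt, int r) {
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  double *src = a, *dst = tmp;

  // x pass: shifted-row accumulation (vectorizable inner loops)
  const int xlo = std::min(r, nx), xhi = std::max(nx - r, xlo);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      const double *s = src + y * (R_xlen_t)nx + z * nxy;
      double *d = dst + y * (R_xlen_t)nx + z * nxy;
      std::fill(d, d + nx, 0.0);
      for (int o = -r; o <= r; ++o) {
        const double wo = wt[o + r];
        const int lo = std::max(0, -o), hi = std::min(nx, nx - o);
        const double *so = s + o;
        for (int x = lo; x < hi; ++x) d[x] += wo * so[x];
      }
      // boundary corrections with reflection
      for (int x = 0; x < xlo; ++x) {
        double acc = 0.0;
        for (int o = -r; o <= r; ++o) acc += wt[o + r] * s[reflect_idx(x + o, nx)];
        d[x] = acc;
      }
      for (int x = xhi; x < nx; ++x) {
        double acc = 0.0;
        for (int o = -r; o <= r; ++o) acc += wt[o + r] * s[reflect_idx(x + o, nx)];
        d[x] = acc;
      }
    }
  }
  std::swap(src, dst);

  // y pass
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      double *d = dst + y * (R_xlen_t)nx + z * nxy;
      std::fill(d, d + nx, 0.0);
      for (int o = -r; o <= r; ++o) {
        const double *s = src + reflect_idx(y + o, ny) * (R_xlen_t)nx + z * nxy;
        const double wo = wt[o + r];
        for (int x = 0; x < nx; ++x) d[x] += wo * s[x];
      }
    }
  }
  std::swap(src, dst);

  // z pass
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      double *d = dst + y * (R_xlen_t)nx + z * nxy;
      std::fill(d, d + nx, 0.0);
      for (int o = -r; o <= r; ++o) {
        const double *s = src + y * (R_xlen_t)nx + reflect_idx(z + o, nz) * nxy;
        const double wo = wt[o + r];
        for (int x = 0; x < nx; ++x) d[x] += wo * s[x];
      }
    }
  }
  std::swap(src, dst);
  // three swaps: result is in `tmp`'s storage if we started in `a`
  if (src != a) std::memcpy(a, src, sizeof(double) * nxy * nz);
}

// [[Rcpp::export]]
NumericVector smooth3_cpp(NumericVector arr, IntegerVector dims,
                          NumericVector w) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = (w.size() - 1) / 2;
  NumericVector a(clone(arr));
  std::vector<double> tmp((R_xlen_t)nx * ny * nz);
  gauss3_raw(a.begin(), tmp.data(), nx, ny, nz, w.begin(), r);
  return a;
}

// sample all three components of a field at one point with shared weights
static inline void tri3_vec(const double *a, R_xlen_t n, int nx, int ny,
                            int nz, double x, double y, double z,
                            double *out) {
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  out[0] = out[1] = out[2] = 0.0;
  for (int dx = 0; dx < 2; ++dx) {
    const int xx = x0 + dx;
    if (xx < 0 || xx >= nx) continue;
    const double wx = dx ? fx : 1.0 - fx;
    if (wx == 0.0) continue;
    for (int dy = 0; dy < 2; ++dy) {
      const int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      const double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dz = 0; dz < 2; ++dz) {
        const int zz = z0 + dz;
        if (zz < 0 || zz >= nz) continue;
        const double w = wx * wy * (dz ? fz : 1.0 - fz);
        if (w == 0.0) continue;
        const R_xlen_t idx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        out[0] += w * a[idx];
        out[1] += w * a[idx + n];
        out[2] += w * a[idx + 2 * n];
      }
    }
  }
}

// One greedy-engine update: u = gauss_{regu}(force * scale) componentwise,
// d <- compose(d, u), then optionally d <- gauss_{regt}(d). Fusing these
// avoids repeated R-level allocation in the iteration hot loop.
// [[Rcpp::export]]
NumericVector update_step_cpp(NumericVector d, NumericVector force,
                              IntegerVector dims, double scale,
                              NumericVector w_regu, NumericVector w_regt,
                              bool do_regu, bool do_regt) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector u(3 * n);
  std::vector<double> tmp(n);
  const double *fo = force.begin();
  double *uv = u.begin();
  for (R_xlen_t i = 0; i < 3 * n; ++i) uv[i] = fo[i] * scale;
  if (do_regu) {
    const int ru = (w_regu.size() - 1) / 2;
    for (int k = 0; k < 3; ++k)
      gauss3_raw(uv + k * n, tmp.data(), nx, ny, nz, w_regu.begin(), ru);
  }
  NumericVector out(3 * n);
  double *ov = out.begin();
  const double *dv = d.begin();
  double s[3];
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x, ++i) {
        tri3_vec(dv, n, nx, ny, nz, x + uv[i], y + uv[i + n],
                 z + uv[i + 2 * n], s);
        ov[i] = uv[i] + s[0];
        ov[i + n] = uv[i + n] + s[1];
        ov[i + 2 * n] = uv[i + 2 * n] + s[2];
      }
    }
  }
  if (do_regt) {
    const int rt = (w_regt.size() - 1) / 2;
    for (int k = 0; k < 3; ++k)
      gauss3_raw(ov + k * n, tmp.data(), nx, ny, nz, w_regt.begin(), rt);
  }
  return out;
}
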