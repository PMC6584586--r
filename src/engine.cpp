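#include <Rcpp.h>
using namespace Rcpp;

static inline double tri(const double *a, int nx, int ny, int nz,
                         double x, double y, double z) {
  // 0-based fractional coordinates; outside -> 0
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  double v = 0.0;
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
        const double wz = dz ? fz : 1.0 - fz;
        if (wz == 0.0) continue;
        v += wx * wy * wz * a[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
      }
    }
  }
  return v;
}

// Warp moving image through displacement field d (pull-back) and return the
// SSD residual force (F - M(x+d)) * grad(M(x+d)) together with the metric.
// [[Rcpp::export]]
List ssd_force_cpp(NumericVector fixed, NumericVector moving,
                   IntegerVector dims, NumericVector d) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double *f = fixed.begin(), *m = moving.begin(), *dd = d.begin();
  NumericVector mw_(n);
  double *mw = mw_.begin();
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i)
        mw[i] = tri(m, nx, ny, nz, x + dd[i], y + dd[i + n], z + dd[i + 2 * n]);
  NumericVector force(3 * n);
  double *fo = force.begin();
  double ssd = 0.0, max_mag2 = 0.0;
  i = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x, ++i) {
        const double r = f[i] - mw[i];
        ssd += r * r;
        // central differences interior, one-sided at faces
        double gx, gy, gz;
        if (nx == 1) gx = 0.0;
        else if (x == 0) gx = mw[i + 1] - mw[i];
        else if (x == nx - 1) gx = mw[i] - mw[i - 1];
        else gx = (mw[i + 1] - mw[i - 1]) / 2.0;
        if (ny == 1) gy = 0.0;
        else if (y == 0) gy = mw[i + nx] - mw[i];
        else if (y == ny - 1) gy = mw[i] - mw[i - nx];
        else gy = (mw[i + nx] - mw[i - nx]) / 2.0;
        const R_xlen_t sz = (R_xlen_t)nx * ny;
        if (nz == 1) gz = 0.0;
        else if (z == 0) gz = mw[i + sz] - mw[i];
        else if (z == nz - 1) gz = mw[i] - mw[i - sz];
        else gz = (mw[i + sz] - mw[i - sz]) / 2.0;
        fo[i] = r * gx;
        fo[i + n] = r * gy;
        fo[i + 2 * n] = r * gz;
        const double m2 = fo[i] * fo[i] + fo[i + n] * fo[i + n] +
          fo[i + 2 * n] * fo[i + 2 * n];
        if (m2 > max_mag2) max_mag2 = m2;
      }
    }
  }
  return List::create(Named("metric") = ssd / (double)n,
                      Named("force") = force,
                      Named("max_mag") = std::sqrt(max_mag2));
}

// Field composition (outer o inner)(x) = inner(x) + outer(x + inner(x));
// the three components share one set of trilinear weights per voxel.
// [[Rcpp::export]]
NumericVector compose3_cpp(NumericVector outer, NumericVector inner,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double *o = outer.begin(), *in = inner.begin();
  NumericVector out(3 * n);
  double *ov = out.begin();
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x, ++i) {
        const double cx = x + in[i], cy = y + in[i + n], cz = z + in[i + 2 * n];
        const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
                  z0 = (int)std::floor(cz);
        const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
        double s0 = 0.0, s1 = 0.0, s2 = 0.0;
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
              const R_xlen_t idx =
                xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
              s0 += w * o[idx];
              s1 += w * o[idx + n];
              s2 += w * o[idx + 2 * n];
            }
          }
        }
        ov[i] = in[i] + s0;
        ov[i + n] = in[i + n] + s1;
        ov[i + 2 * n] = in[i + 2 * n] + s2;
      }
    }
  }
  return out;
}

// Warp a scalar image through a displacement field (pull-back, trilinear).
// [[Rcpp::export]]
NumericVector warp3_cpp(NumericVector arr, IntegerVector dims,
                        NumericVector d) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double *a = arr.begin(), *dd = d.begin();
  NumericVector out(n);
  double *ov = out.begin();
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i)
        ov[i] = tri(a, nx, ny, nz, x + dd[i], y + dd[i + n], z + dd[i + 2 * n]);
  return out;
}
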