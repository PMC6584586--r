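#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3-D array at fractional 1-based voxel coordinates.
// Samples outside the grid contribute 0 (background), so values fade to 0
// across the boundary instead of being clamped.
// [[Rcpp::export]]
NumericVector interp3_linear(NumericVector arr, IntegerVector dims,
                             NumericVector xi, NumericVector yi,
                             NumericVector zi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  const double *a = arr.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    const double x = xi[t] - 1.0, y = yi[t] - 1.0, z = zi[t] - 1.0;
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
    out[t] = v;
  }
  return out;
}

// Nearest-neighbour sampling; out-of-grid samples return 0.
// [[Rcpp::export]]
NumericVector interp3_nearest(NumericVector arr, IntegerVector dims,
                              NumericVector xi, NumericVector yi,
                              NumericVector zi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  const double *a = arr.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    const int xx = (int)std::lround(xi[t]) - 1;
    const int yy = (int)std::lround(yi[t]) - 1;
    const int zz = (int)std::lround(zi[t]) - 1;
    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
      out[t] = 0.0;
    } else {
      out[t] = a[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
    }
  }
  return out;
}
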