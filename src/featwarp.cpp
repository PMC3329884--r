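#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear index into an (nx, ny, nz) array, 0-based components.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Orientation-histogram descriptors for a set of feature points.
//
// gx, gy, gz: per-voxel gradient components (image units per voxel step)
// dims:       grid shape (nx, ny, nz)
// pts:        n x 3 matrix of 1-based voxel indices (window must fit)
// mode2d:     single xy plane, 8x8 window, 4 quadrants -> 32 components
// countWeight: accumulate 1 per nonzero projection instead of its magnitude
//
// Component order (3D): quadrant (0..7) x plane (xy, yz, zx) x bin (0..7),
// quadrant q = (dx>=0) + 2*(dy>=0) + 4*(dz>=0) over window offsets -4..3.
// Plane angles: xy = atan2(gy,gx); yz = atan2(gz,gy); zx = atan2(gz,gx);
// 8 bins of 45 degrees, half-open [45b, 45(b+1)).
// [[Rcpp::export]]
NumericMatrix cpp_descriptors(NumericVector gx, NumericVector gy,
                              NumericVector gz, IntegerVector dims,
                              IntegerMatrix pts, bool mode2d,
                              bool countWeight) {
  const int nx = dims[0], ny = dims[1];
  const int n = pts.nrow();
  const int ncomp = mode2d ? 32 : 192;
  NumericMatrix out(n, ncomp);
  const double rad2deg = 180.0 / M_PI;

  for (int p = 0; p < n; ++p) {
    const int ci = pts(p, 0) - 1, cj = pts(p, 1) - 1, ck = pts(p, 2) - 1;
    const int zlo = mode2d ? 0 : -4, zhi = mode2d ? 0 : 3;
    for (int dz = zlo; dz <= zhi; ++dz) {
      for (int dy = -4; dy <= 3; ++dy) {
        for (int dx = -4; dx <= 3; ++dx) {
          R_xlen_t v = lin(ci + dx, cj + dy, ck + dz, nx, ny);
          const double vgx = gx[v], vgy = gy[v], vgz = gz[v];
          int quad = (dx >= 0 ? 1 : 0) + (dy >= 0 ? 2 : 0);
          if (!mode2d) quad += (dz >= 0 ? 4 : 0);
          const int nplanes = mode2d ? 1 : 3;
          for (int pl = 0; pl < nplanes; ++pl) {
            double c1, c2; // angle measured from c1 axis
            if (pl == 0)      { c1 = vgx; c2 = vgy; } // xy
            else if (pl == 1) { c1 = vgy; c2 = vgz; } // yz
            else              { c1 = vgx; c2 = vgz; } // zx
            const double mag = std::sqrt(c1 * c1 + c2 * c2);
            if (mag <= 0.0) continue;
            double ang = std::atan2(c2, c1) * rad2deg;
            if (ang < 0.0) ang += 360.0;
            int bin = (int)(ang / 45.0);
            if (bin > 7) bin = 7; // guard against rounding at 360
            const int idx = mode2d ? quad * 8 + bin
                                   : quad * 24 + pl * 8 + bin;
            out(p, idx) += countWeight ? 1.0 : mag;
          }
        }
      }
    }
  }
  return out;
}

// Greedy non-maximum suppression. coords (n x 3, mm) must already be
// sorted by descending priority (ties broken upstream). Returns 1-based
// indices of the retained rows, at most max_points of them.
// [[Rcpp::export]]
IntegerVector cpp_nms(NumericMatrix coords, double radius, int max_points) {
  const int n = coords.nrow();
  const double r2 = radius * radius;
  std::vector<int> keep;
  std::vector<double> kx, ky, kz;
  keep.reserve(std::min(n, max_points));
  for (int i = 0; i < n; ++i) {
    if ((int)keep.size() >= max_points) break;
    const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    bool ok = true;
    if (r2 > 0.0) {
      for (size_t a = 0; a < keep.size(); ++a) {
        const double dx = x - kx[a], dy = y - ky[a], dz = z - kz[a];
        if (dx * dx + dy * dy + dz * dz <= r2) { ok = false; break; }
      }
    }
    if (ok) {
      keep.push_back(i + 1);
      kx.push_back(x); ky.push_back(y); kz.push_back(z);
    }
  }
  return wrap(keep);
}

// Evaluate a fitted thin-plate spline at a set of points.
// pts: m x d query points; src: n x d control points; W: n x d kernel
// weights; A: (d+1) x d affine coefficients (intercept first).
// kernelType 0: U(r) = r^2 log(r^2); kernelType 1: U(r) = r.
// [[Rcpp::export]]
NumericMatrix cpp_tps_eval(NumericMatrix pts, NumericMatrix src,
                           NumericMatrix W, NumericMatrix A,
                           int kernelType) {
  const int m = pts.nrow(), n = src.nrow(), d = pts.ncol();
  NumericMatrix out(m, d);
  std::vector<double> u(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double r2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double t = src(j, c) - pts(i, c);
        r2 += t * t;
      }
      if (r2 <= 0.0) u[j] = 0.0;
      else u[j] = kernelType == 0 ? r2 * std::log(r2) : std::sqrt(r2);
    }
    for (int c = 0; c < d; ++c) {
      double acc = A(0, c);
      for (int k = 0; k < d; ++k) acc += A(k + 1, c) * pts(i, k);
      for (int j = 0; j < n; ++j) acc += W(j, c) * u[j];
      out(i, c) = acc;
    }
  }
  return out;
}

// Trilinear sampling of a scalar volume at physical points.
// Points outside the grid's physical extent get `fill`. Degenerate axes
// (size 1) interpolate as constant along that axis.
// [[Rcpp::export]]
NumericVector cpp_sample_linear(NumericVector data, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = pts.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    double v[3];
    bool outside = false;
    const int nn[3] = {nx, ny, nz};
    for (int c = 0; c < 3; ++c) {
      v[c] = (pts(p, c) - origin[c]) / spacing[c];
      if (nn[c] == 1) v[c] = 0.0;
      else if (v[c] < 0.0 || v[c] > nn[c] - 1) { outside = true; break; }
    }
    if (outside) { out[p] = fill; continue; }
    int i0[3]; double f[3];
    for (int c = 0; c < 3; ++c) {
      i0[c] = (int)std::floor(v[c]);
      if (i0[c] > nn[c] - 2) i0[c] = nn[c] >= 2 ? nn[c] - 2 : 0;
      f[c] = v[c] - i0[c];
      if (nn[c] == 1) { i0[c] = 0; f[c] = 0.0; }
    }
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      const double wz = dz ? f[2] : 1.0 - f[2];
      if (wz == 0.0) continue;
      const int k = nz == 1 ? 0 : i0[2] + dz;
      for (int dy = 0; dy <= 1; ++dy) {
        const double wy = dy ? f[1] : 1.0 - f[1];
        if (wy == 0.0) continue;
        const int j = ny == 1 ? 0 : i0[1] + dy;
        for (int dx = 0; dx <= 1; ++dx) {
          const double wx = dx ? f[0] : 1.0 - f[0];
          if (wx == 0.0) continue;
          const int i = nx == 1 ? 0 : i0[0] + dx;
          acc += wx * wy * wz * data[lin(i, j, k, nx, ny)];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}
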