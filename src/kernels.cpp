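#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact 3-D Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower envelope of parabolas, anisotropic spacing in mm.
// Input: integer array (non-zero = feature set). Output: distance in mm to
// the nearest feature voxel centre (0 inside the feature set).
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  // lower envelope over columns with finite f only
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    double qq = q * step;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      double vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s > z[k]) break;
      k--;
      if (k < 0) break;
    }
    k++;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite column in this line
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < q * step) j++;
    double dq = q * step - v[j] * step;
    d[q] = dq * dq + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector edt3d_cpp(IntegerVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); i++) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      size_t base = (size_t)j * nx + (size_t)k * nx * ny;
      bool any = false;
      for (int i = 0; i < nx; i++) { f[i] = g[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) g[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      size_t base = (size_t)i + (size_t)k * nx * ny;
      bool any = false;
      for (int j = 0; j < ny; j++) { f[j] = g[base + (size_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) g[base + (size_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      size_t base = (size_t)i + (size_t)j * nx;
      bool any = false;
      for (int k = 0; k < nz; k++) { f[k] = g[base + (size_t)k * nx * ny]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) g[base + (size_t)k * nx * ny] = d[k];
    }

  NumericVector out((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); i++)
    out[i] = (g[i] == INF) ? INF : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Convolution gridding of non-Cartesian k-space samples onto a Cartesian
// grid with a separable Hann (raised-cosine) kernel of full width `width`
// grid cells. Sample coordinates are in grid-cell units relative to the
// k-space centre; the output grid is in wrap-around (FFT) order with DC at
// index [0,0,0]. Out-of-range kernel taps wrap periodically.
// ---------------------------------------------------------------------------

static inline double hann(double u, double halfw) {
  if (std::fabs(u) >= halfw) return 0.0;
  return 0.5 * (1.0 + std::cos(M_PI * u / halfw));
}

// [[Rcpp::export]]
ComplexVector grid_kspace_cpp(NumericMatrix kc, ComplexVector samples,
                              IntegerVector gridsize, double width) {
  int nx = gridsize[0], ny = gridsize[1], nz = gridsize[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<double> re(ntot, 0.0), im(ntot, 0.0);
  int hw = (int)std::ceil(width / 2.0);
  double halfw = width / 2.0;
  int ns = samples.size();
  for (int s = 0; s < ns; s++) {
    double kx = kc(s, 0), ky = kc(s, 1), kz = kc(s, 2);
    double sr = samples[s].r, si = samples[s].i;
    int cx = (int)std::floor(kx), cy = (int)std::floor(ky), cz = (int)std::floor(kz);
    for (int dz = -hw + 1; dz <= hw; dz++) {
      double wz = hann(cz + dz - kz, halfw);
      if (wz == 0.0) continue;
      int iz = ((cz + dz) % nz + nz) % nz;
      for (int dy = -hw + 1; dy <= hw; dy++) {
        double wy = hann(cy + dy - ky, halfw);
        if (wy == 0.0) continue;
        int iy = ((cy + dy) % ny + ny) % ny;
        double wzy = wz * wy;
        for (int dx = -hw + 1; dx <= hw; dx++) {
          double wx = hann(cx + dx - kx, halfw);
          if (wx == 0.0) continue;
          int ix = ((cx + dx) % nx + nx) % nx;
          size_t idx = (size_t)ix + (size_t)iy * nx + (size_t)iz * nx * ny;
          re[idx] += sr * wzy * wx;
          im[idx] += si * wzy * wx;
        }
      }
    }
  }
  ComplexVector out(ntot);
  for (size_t i = 0; i < ntot; i++) { out[i].r = re[i]; out[i].i = im[i]; }
  out.attr("dim") = gridsize;
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation of a complex 3-D array at fractional 0-based
// coordinates, with periodic wrap-around (used to sample an oversampled
// Cartesian spectrum at radial trajectory points).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
ComplexVector interp3_complex_wrap_cpp(ComplexVector vol, NumericMatrix pts) {
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  ComplexVector out(n);
  for (int s = 0; s < n; s++) {
    double x = pts(s, 0), y = pts(s, 1), z = pts(s, 2);
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double accr = 0.0, acci = 0.0;
    for (int dz = 0; dz <= 1; dz++) {
      int iz = ((z0 + dz) % nz + nz) % nz;
      double wz = dz ? fz : 1 - fz;
      for (int dy = 0; dy <= 1; dy++) {
        int iy = ((y0 + dy) % ny + ny) % ny;
        double wy = dy ? fy : 1 - fy;
        for (int dx = 0; dx <= 1; dx++) {
          int ix = ((x0 + dx) % nx + nx) % nx;
          double w = wz * wy * (dx ? fx : 1 - fx);
          size_t idx = (size_t)ix + (size_t)iy * nx + (size_t)iz * nx * ny;
          accr += w * vol[idx].r;
          acci += w * vol[idx].i;
        }
      }
    }
    out[s].r = accr;
    out[s].i = acci;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation of a real 3-D array at fractional 1-based
// coordinates; points outside the grid return `fill`. Used for image
// resampling under rigid transforms.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector interp3_real_cpp(NumericVector vol, NumericMatrix pts,
                               double fill) {
  IntegerVector dims = vol.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int s = 0; s < n; s++) {
    double x = pts(s, 0) - 1.0, y = pts(s, 1) - 1.0, z = pts(s, 2) - 1.0;
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[s] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; dz++) {
      double wz = dz ? fz : 1 - fz;
      for (int dy = 0; dy <= 1; dy++) {
        double wy = dy ? fy : 1 - fy;
        for (int dx = 0; dx <= 1; dx++) {
          double w = wz * wy * (dx ? fx : 1 - fx);
          size_t idx = (size_t)(x0 + dx) + (size_t)(y0 + dy) * nx +
                       (size_t)(z0 + dz) * nx * ny;
          acc += w * vol[idx];
        }
      }
    }
    out[s] = acc;
  }
  return out;
}
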