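#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (lower envelope of parabolas), sample spacing h.
// f: input squared distances at integer indices; d: output; work buffers v, z.
static void dt1d(const double *f, double *d, int n, double h2,
                 std::vector<int> &v, std::vector<double> &z) {
  int q0 = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] < INF) { q0 = q; break; }
  }
  if (q0 < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] - f[v[k]]) / h2 + (double)q * q - (double)v[k] * v[k]) /
               (2.0 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] - f[v[k]]) / h2 + (double)q * q - (double)v[k] * v[k]) /
          (2.0 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// foreground voxel center, with anisotropic spacing. Felzenszwalb-Huttenlocher
// separable transform applied along the three axes.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis x: stride 1
  double h2 = spacing[0] * spacing[0];
  for (int zi = 0; zi < nz; ++zi)
    for (int yi = 0; yi < ny; ++yi) {
      R_xlen_t base = (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi);
      for (int xi = 0; xi < nx; ++xi) f[xi] = out[base + xi];
      dt1d(f.data(), d.data(), nx, h2, v, z);
      for (int xi = 0; xi < nx; ++xi) out[base + xi] = d[xi];
    }
  // axis y: stride nx
  h2 = spacing[1] * spacing[1];
  for (int zi = 0; zi < nz; ++zi)
    for (int xi = 0; xi < nx; ++xi) {
      R_xlen_t base = xi + (R_xlen_t)nx * ny * zi;
      for (int yi = 0; yi < ny; ++yi) f[yi] = out[base + (R_xlen_t)nx * yi];
      dt1d(f.data(), d.data(), ny, h2, v, z);
      for (int yi = 0; yi < ny; ++yi) out[base + (R_xlen_t)nx * yi] = d[yi];
    }
  // axis z: stride nx*ny
  h2 = spacing[2] * spacing[2];
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int yi = 0; yi < ny; ++yi)
    for (int xi = 0; xi < nx; ++xi) {
      R_xlen_t base = xi + (R_xlen_t)nx * yi;
      for (int zi = 0; zi < nz; ++zi) f[zi] = out[base + sz * zi];
      dt1d(f.data(), d.data(), nz, h2, v, z);
      for (int zi = 0; zi < nz; ++zi) out[base + sz * zi] = d[zi];
    }
  return out;
}
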