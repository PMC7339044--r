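#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable over the three axes, anisotropy-aware (per-axis sample spacing).

static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  // Parabolas with infinite height can never be the lower envelope once a
  // finite one exists on the line, so they are skipped outright; the caller
  // guarantees at least one finite sample.
  int q0 = 0;
  while (f[q0] == INF) ++q0;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// mask: logical array (column-major, dims = dim); spacing: mm per axis.
// Returns squared distance (mm^2) from each voxel centre to the nearest
// TRUE voxel centre; Inf if the mask is empty.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (x): stride 1
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // axis 2 (y): stride nx
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // axis 3 (z): stride nx*ny
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = out[base + k * sxy]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) out[base + k * sxy] = d[k];
    }
  return out;
}
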