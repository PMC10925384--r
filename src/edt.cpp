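#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas), sample
// positions at i * s so anisotropic voxel spacing is exact
static void dt1d(double* f, int n, double s, double* d,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double sq = (double)q * s, sv;
    double inter;
    while (true) {
      sv = (double)v[k] * s;
      inter = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
      if (inter <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) {  // empty line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    const double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// Euclidean distance (world units) from every voxel to the nearest feature
// voxel center; feature: integer array (nonzero = feature); spacing: mm/voxel
// [[Rcpp::export(name = ".edt3")]]
NumericVector edt3(IntegerVector feature, IntegerVector dims,
                   NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<double> D(N);
  for (R_xlen_t i = 0; i < N; ++i) D[i] = feature[i] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      const R_xlen_t base = ((R_xlen_t)zz * ny + yy) * nx;
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      dt1d(f.data(), nx, spacing[0], d.data(), v, z);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)zz * ny * nx + x;
      for (int y = 0; y < ny; ++y) f[y] = D[base + (R_xlen_t)y * nx];
      dt1d(f.data(), ny, spacing[1], d.data(), v, z);
      for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = d[y];
    }
  // z pass
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)yy * nx + x;
      for (int zz = 0; zz < nz; ++zz) f[zz] = D[base + sz * zz];
      dt1d(f.data(), nz, spacing[2], d.data(), v, z);
      for (int zz = 0; zz < nz; ++zz) D[base + sz * zz] = d[zz];
    }

  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = std::sqrt(D[i]);
  out.attr("dim") = dims;
  return out;
}
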