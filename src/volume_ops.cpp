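#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Resample a 3D volume onto a new grid. M is a 4x4 matrix mapping 0-based
// output voxel indices to 0-based source voxel indices. disp, if non-NULL,
// is a (3 x Nout) displacement (in source voxel units) added after M.
// mode: 0 = nearest neighbor, 1 = trilinear. clamp_edges: clamp sample
// coordinates into the source grid instead of using the background value
// (used when upsampling smooth control-point fields).
// [[Rcpp::export(name = ".resample3")]]
NumericVector resample3(NumericVector src, IntegerVector sdims,
                        IntegerVector odims, NumericMatrix M,
                        Nullable<NumericMatrix> disp, int mode,
                        double background, bool clamp_edges) {
  const int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  const R_xlen_t Nout = (R_xlen_t)ox * oy * oz;
  NumericVector out(Nout);
  const double* s = src.begin();
  double* o = out.begin();
  const double* d = nullptr;
  if (disp.isNotNull()) {
    NumericMatrix dm(disp);
    if (dm.nrow() != 3 || dm.ncol() != Nout) stop("displacement must be 3 x Nout");
    d = dm.begin();
  }
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);

  R_xlen_t v = 0;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x, ++v) {
        double px = m00 * x + m01 * y + m02 * z + m03;
        double py = m10 * x + m11 * y + m12 * z + m13;
        double pz = m20 * x + m21 * y + m22 * z + m23;
        if (d) { px += d[3 * v]; py += d[3 * v + 1]; pz += d[3 * v + 2]; }
        if (clamp_edges) {
          px = std::min(std::max(px, 0.0), (double)(sx - 1));
          py = std::min(std::max(py, 0.0), (double)(sy - 1));
          pz = std::min(std::max(pz, 0.0), (double)(sz - 1));
        }
        if (mode == 0) {
          const int ix = (int)std::lround(px);
          const int iy = (int)std::lround(py);
          const int iz = (int)std::lround(pz);
          if (ix < 0 || ix >= sx || iy < 0 || iy >= sy || iz < 0 || iz >= sz)
            o[v] = background;
          else
            o[v] = s[((R_xlen_t)iz * sy + iy) * sx + ix];
        } else {
          const int ix = (int)std::floor(px);
          const int iy = (int)std::floor(py);
          const int iz = (int)std::floor(pz);
          const double fx = px - ix, fy = py - iy, fz = pz - iz;
          double acc = 0.0;
          for (int cz = 0; cz < 2; ++cz)
            for (int cy = 0; cy < 2; ++cy)
              for (int cx = 0; cx < 2; ++cx) {
                const double wgt = (cx ? fx : 1.0 - fx) * (cy ? fy : 1.0 - fy) *
                                   (cz ? fz : 1.0 - fz);
                if (wgt == 0.0) continue;
                const int jx = ix + cx, jy = iy + cy, jz = iz + cz;
                double val;
                if (jx < 0 || jx >= sx || jy < 0 || jy >= sy || jz < 0 || jz >= sz)
                  val = background;
                else
                  val = s[((R_xlen_t)jz * sy + jy) * sx + jx];
                acc += wgt * val;
              }
          o[v] = acc;
        }
      }
  out.attr("dim") = odims;
  return out;
}

// separable Gaussian blur; sigma per axis in voxel units; kernels truncated
// at 3 sigma and renormalized at the edges
static void blur_axis(std::vector<double>& buf, std::vector<double>& tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double ks = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (i * i) / (sigma * sigma));
    ks += k[i + r];
  }
  for (double& w : k) w /= ks;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  const int b1 = axis == 0 ? 1 : 0;
  const int b2 = axis == 2 ? 1 : 2;
  for (int j2 = 0; j2 < n[b2]; ++j2)
    for (int j1 = 0; j1 < n[b1]; ++j1) {
      const R_xlen_t base = stride[b1] * j1 + stride[b2] * j2;
      for (int i = 0; i < na; ++i) {
        double acc = 0, wsum = 0;
        const int lo = std::max(0, i - r), hi = std::min(na - 1, i + r);
        for (int j = lo; j <= hi; ++j) {
          const double w = k[j - i + r];
          acc += w * buf[base + sa * j];
          wsum += w;
        }
        tmp[base + sa * i] = acc / wsum;
      }
    }
  std::swap(buf, tmp);
}

// [[Rcpp::export(name = ".gaussian_blur3")]]
NumericVector gaussian_blur3(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(N);
  blur_axis(buf, tmp, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(buf, tmp, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(buf, tmp, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dims;
  return out;
}

// mean-pool by integer factor then nearest-upsample back to the input grid
// (partial edge blocks average over the voxels present)
// [[Rcpp::export(name = ".block_down_up")]]
NumericVector block_down_up(NumericVector vol, IntegerVector dims, int f) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (f < 1) stop("factor must be >= 1");
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* s = vol.begin();
  double* o = out.begin();
  for (int bz = 0; bz < nz; bz += f)
    for (int by = 0; by < ny; by += f)
      for (int bx = 0; bx < nx; bx += f) {
        const int ez = std::min(bz + f, nz), ey = std::min(by + f, ny),
                  ex = std::min(bx + f, nx);
        double acc = 0;
        int cnt = 0;
        for (int z = bz; z < ez; ++z)
          for (int y = by; y < ey; ++y)
            for (int x = bx; x < ex; ++x, ++cnt)
              acc += s[((R_xlen_t)z * ny + y) * nx + x];
        const double mean = acc / cnt;
        for (int z = bz; z < ez; ++z)
          for (int y = by; y < ey; ++y)
            for (int x = bx; x < ex; ++x)
              o[((R_xlen_t)z * ny + y) * nx + x] = mean;
      }
  out.attr("dim") = dims;
  return out;
}
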