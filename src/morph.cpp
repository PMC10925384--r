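#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// offsets for 6- (face) and 26- (face+edge+corner) connectivity
static int neighbor_offsets(int conn, int nx, int ny, int off[][3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ad == 0) continue;
        if (conn == 6 && ad != 1) continue;
        off[n][0] = dx; off[n][1] = dy; off[n][2] = dz;
        ++n;
      }
  return n;
}

// iterated binary dilation (op = 1) or erosion (op = 0); voxels outside the
// grid count as background unless border_fg is set (then erosion treats them
// as foreground, making closing extensive at the volume border)
// [[Rcpp::export(name = ".binary_morph")]]
LogicalVector binary_morph(LogicalVector mask, IntegerVector dims, int op,
                           int iters, int conn, bool border_fg = false) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<char> a(N), b(N);
  for (R_xlen_t i = 0; i < N; ++i) a[i] = mask[i] ? 1 : 0;
  int off[26][3];
  const int no = neighbor_offsets(conn, nx, ny, off);
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t v = ((R_xlen_t)z * ny + y) * nx + x;
          char val = a[v];
          if (op == 1 && !val) {  // dilate: background voxel gains if any neighbor set
            for (int k = 0; k < no && !val; ++k) {
              const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              if (a[((R_xlen_t)zz * ny + yy) * nx + xx]) val = 1;
            }
          } else if (op == 0 && val) {  // erode: foreground lost if any neighbor clear
            for (int k = 0; k < no && val; ++k) {
              const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
                if (!border_fg) { val = 0; break; }
                continue;
              }
              if (!a[((R_xlen_t)zz * ny + yy) * nx + xx]) val = 0;
            }
          }
          b[v] = val;
        }
    std::swap(a, b);
  }
  LogicalVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = a[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// connected-component labels (0 stays 0); BFS, 6- or 26-connectivity
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N);
  int off[26][3];
  const int no = neighbor_offsets(conn, nx, ny, off);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t seed = 0; seed < N; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    lab[seed] = ++next;
    q.push(seed);
    while (!q.empty()) {
      const R_xlen_t v = q.front();
      q.pop();
      const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < no; ++k) {
        const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t u = ((R_xlen_t)zz * ny + yy) * nx + xx;
        if (mask[u] && !lab[u]) { lab[u] = next; q.push(u); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// background voxels (mask == 0) reachable from the volume border by
// face-connectivity; holes are background voxels with outside == FALSE
// [[Rcpp::export(name = ".outside_background")]]
LogicalVector outside_background(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  LogicalVector out(N);
  std::vector<char> seen(N, 0);
  std::queue<R_xlen_t> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 && z != 0 && z != nz - 1)
          continue;
        const R_xlen_t v = ((R_xlen_t)z * ny + y) * nx + x;
        if (!mask[v] && !seen[v]) { seen[v] = 1; q.push(v); }
      }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    const R_xlen_t v = q.front();
    q.pop();
    const int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
    for (int k = 0; k < 6; ++k) {
      const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const R_xlen_t u = ((R_xlen_t)zz * ny + yy) * nx + xx;
      if (!mask[u] && !seen[u]) { seen[u] = 1; q.push(u); }
    }
  }
  for (R_xlen_t i = 0; i < N; ++i) out[i] = seen[i] != 0;
  out.attr("dim") = dims;
  return out;
}
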