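#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f holds squared distances along the line
// (INF marks positions that are not sites yet); d receives the envelope.
// Grid spacing is 1 in voxel units; per-axis anisotropy enters through w2,
// the squared spacing weight.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance transform of a 3D logical array (dims ny,nx,nz,
// column-major). For each TRUE voxel: squared distance (in weighted voxel
// units) to the nearest FALSE voxel; FALSE voxels map to 0. Axes with
// transform_dims[i] == FALSE do not propagate distance (e.g. per-slice 2D
// transforms skip z, leaving the longitudinal faces "open"). With isotropic
// weights (1,1,1) every output is an exact small integer in a double.
// [[Rcpp::export]]
NumericVector cpp_edt2(LogicalVector phase, IntegerVector dim,
                       LogicalVector transform_dims, NumericVector w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = phase[i] ? INF : 0.0;

  int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  if (transform_dims[0] && ny > 1) {  // along y, stride 1
    for (int iz = 0; iz < nz; ++iz) {
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t base = (R_xlen_t)iz * ny * nx + (R_xlen_t)ix * ny;
        for (int iy = 0; iy < ny; ++iy) f[iy] = out[base + iy];
        dt1d(f, d, v, z, ny, w2[0]);
        for (int iy = 0; iy < ny; ++iy) out[base + iy] = d[iy];
      }
    }
  }
  if (transform_dims[1] && nx > 1) {  // along x, stride ny
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) {
        R_xlen_t base = (R_xlen_t)iz * ny * nx + iy;
        for (int ix = 0; ix < nx; ++ix) f[ix] = out[base + (R_xlen_t)ix * ny];
        dt1d(f, d, v, z, nx, w2[1]);
        for (int ix = 0; ix < nx; ++ix) out[base + (R_xlen_t)ix * ny] = d[ix];
      }
    }
  }
  if (transform_dims[2] && nz > 1) {  // along z, stride ny*nx
    R_xlen_t snx = (R_xlen_t)ny * nx;
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) {
        R_xlen_t base = (R_xlen_t)ix * ny + iy;
        for (int iz = 0; iz < nz; ++iz) f[iz] = out[base + iz * snx];
        dt1d(f, d, v, z, nz, w2[2]);
        for (int iz = 0; iz < nz; ++iz) out[base + iz * snx] = d[iz];
      }
    }
  }
  return out;
}
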