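#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Maximal-inscribed-sphere local thickness (Hildebrand-Ruegsegger) on a 3D
// void mask, given the squared EDT (exact integers, isotropic voxel units).
// Definition implemented: thickness(x) = max over void voxels c of
// 2*sqrt(edt2[c]) such that |x - c|^2 < edt2[c] (strict), i.e. the diameter of
// the largest EDT sphere containing x. An isolated voxel (edt2 = 1) therefore
// has thickness 2 voxels.
//
// Voxels whose sphere is provably contained in a 26-neighbour's sphere
// (r_nb >= r + dist, continuous containment implies discrete containment under
// the strict-< membership rule) are skipped as paint sources; this is the
// distance-ridge reduction and does not change the result.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector edt2, IntegerVector dim) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t snx = (R_xlen_t)ny * nx;
  R_xlen_t n = snx * nz;
  NumericVector out(n);

  // collect void voxels (edt2 > 0)
  std::vector<R_xlen_t> idx;
  idx.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i)
    if (edt2[i] > 0.0) idx.push_back(i);
  if (idx.empty()) return out;

  // neighbour offsets and centre distances
  const double sq2 = std::sqrt(2.0), sq3 = std::sqrt(3.0);
  int noff[26][3];
  double ndist[26];
  int m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        noff[m][0] = dy; noff[m][1] = dx; noff[m][2] = dz;
        int a = std::abs(dy) + std::abs(dx) + std::abs(dz);
        ndist[m] = (a == 1) ? 1.0 : (a == 2 ? sq2 : sq3);
        ++m;
      }

  // ridge: keep voxels not dominated by any neighbour
  std::vector<R_xlen_t> ridge;
  ridge.reserve(idx.size() / 4 + 16);
  for (size_t t = 0; t < idx.size(); ++t) {
    R_xlen_t i = idx[t];
    int iy = (int)(i % ny);
    int ix = (int)((i / ny) % nx);
    int iz = (int)(i / snx);
    double r = std::sqrt(edt2[i]);
    bool dominated = false;
    for (int q = 0; q < 26; ++q) {
      int jy = iy + noff[q][0], jx = ix + noff[q][1], jz = iz + noff[q][2];
      if (jy < 0 || jy >= ny || jx < 0 || jx >= nx || jz < 0 || jz >= nz)
        continue;
      R_xlen_t j = (R_xlen_t)jz * snx + (R_xlen_t)jx * ny + jy;
      if (edt2[j] <= 0.0) continue;
      if (std::sqrt(edt2[j]) >= r + ndist[q] + 1e-9) { dominated = true; break; }
    }
    if (!dominated) ridge.push_back(i);
  }

  // paint larger spheres first so most writes are no-ops
  std::sort(ridge.begin(), ridge.end(),
            [&](R_xlen_t a, R_xlen_t b) { return edt2[a] > edt2[b]; });

  for (size_t t = 0; t < ridge.size(); ++t) {
    R_xlen_t i = ridge[t];
    int iy = (int)(i % ny);
    int ix = (int)((i / ny) % nx);
    int iz = (int)(i / snx);
    double r2 = edt2[i];
    double th = 2.0 * std::sqrt(r2);
    int rad = (int)std::ceil(std::sqrt(r2)) ;
    int z0 = std::max(0, iz - rad), z1 = std::min(nz - 1, iz + rad);
    int x0 = std::max(0, ix - rad), x1 = std::min(nx - 1, ix + rad);
    int y0 = std::max(0, iy - rad), y1 = std::min(ny - 1, iy + rad);
    for (int jz = z0; jz <= z1; ++jz) {
      double dz2 = (double)(jz - iz) * (jz - iz);
      if (dz2 >= r2) continue;
      for (int jx = x0; jx <= x1; ++jx) {
        double dxz2 = dz2 + (double)(jx - ix) * (jx - ix);
        if (dxz2 >= r2) continue;
        R_xlen_t base = (R_xlen_t)jz * snx + (R_xlen_t)jx * ny;
        for (int jy = y0; jy <= y1; ++jy) {
          double d2 = dxz2 + (double)(jy - iy) * (jy - iy);
          if (d2 < r2 && out[base + jy] < th) out[base + jy] = th;
        }
      }
    }
  }
  return out;
}
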