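#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Flood-fill connected-component labeling of a 2D logical matrix
// (column-major, ny x nx), 4- or 8-connectivity. Labels are 1..k in scan
// order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label2d(LogicalVector mask, int ny, int nx, bool eight) {
  IntegerVector lab(ny * nx);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  const int off4y[] = {-1, 1, 0, 0}, off4x[] = {0, 0, -1, 1};
  const int off8y[] = {-1, 1, 0, 0, -1, -1, 1, 1}, off8x[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = eight ? 8 : 4;
  const int* offy = eight ? off8y : off4y;
  const int* offx = eight ? off8x : off4x;
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      int i = ix * ny + iy;
      if (!mask[i] || lab[i] != 0) continue;
      ++next;
      lab[i] = next;
      stack.push_back(i);
      while (!stack.empty()) {
        int j = stack.back();
        stack.pop_back();
        int jy = j % ny, jx = j / ny;
        for (int q = 0; q < nnb; ++q) {
          int ky = jy + offy[q], kx = jx + offx[q];
          if (ky < 0 || ky >= ny || kx < 0 || kx >= nx) continue;
          int k = kx * ny + ky;
          if (mask[k] && lab[k] == 0) {
            lab[k] = next;
            stack.push_back(k);
          }
        }
      }
    }
  }
  return lab;
}

// Per-transverse-slice despeckle of a 3D logical array (ny, nx, nz): on each
// fixed-z slice, every foreground component with strictly fewer than
// min_pixels pixels is set to background. Idempotent by construction.
// [[Rcpp::export]]
LogicalVector cpp_despeckle2d(LogicalVector mask, IntegerVector dim,
                              int min_pixels, bool eight) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t snx = (R_xlen_t)ny * nx;
  LogicalVector out(clone(mask));
  std::vector<int> lab(snx), stack;
  stack.reserve(256);
  const int off4y[] = {-1, 1, 0, 0}, off4x[] = {0, 0, -1, 1};
  const int off8y[] = {-1, 1, 0, 0, -1, -1, 1, 1}, off8x[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = eight ? 8 : 4;
  const int* offy = eight ? off8y : off4y;
  const int* offx = eight ? off8x : off4x;
  for (int iz = 0; iz < nz; ++iz) {
    R_xlen_t base = iz * snx;
    std::fill(lab.begin(), lab.end(), 0);
    std::vector<int> sizes(1, 0);
    int next = 0;
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) {
        int i = ix * ny + iy;
        if (!out[base + i] || lab[i] != 0) continue;
        ++next;
        sizes.push_back(0);
        lab[i] = next;
        sizes[next] = 1;
        stack.push_back(i);
        while (!stack.empty()) {
          int j = stack.back();
          stack.pop_back();
          int jy = j % ny, jx = j / ny;
          for (int q = 0; q < nnb; ++q) {
            int ky = jy + offy[q], kx = jx + offx[q];
            if (ky < 0 || ky >= ny || kx < 0 || kx >= nx) continue;
            int k = kx * ny + ky;
            if (out[base + k] && lab[k] == 0) {
              lab[k] = next;
              ++sizes[next];
              stack.push_back(k);
            }
          }
        }
      }
    }
    for (R_xlen_t i = 0; i < snx; ++i)
      if (lab[i] != 0 && sizes[lab[i]] < min_pixels) out[base + i] = FALSE;
  }
  return out;
}

// Paint a set of axis-aligned circular canals into an integer label volume.
// labels: modified in place copy. disks: for each canal, the flat (y,x)
// pixel index list (1-based) of its cross-section; z ranges are inclusive
// 1-based voxel indices. value painted = canal id + 1.
// [[Rcpp::export]]
IntegerVector cpp_paint_canals(IntegerVector labels, IntegerVector dim,
                               List disks, IntegerVector z0, IntegerVector z1,
                               IntegerVector ids) {
  int ny = dim[0], nx = dim[1];
  R_xlen_t snx = (R_xlen_t)ny * nx;
  IntegerVector out(clone(labels));
  for (int c = 0; c < disks.size(); ++c) {
    IntegerVector px = disks[c];
    int val = ids[c] + 1;
    for (int iz = z0[c] - 1; iz <= z1[c] - 1; ++iz) {
      R_xlen_t base = (R_xlen_t)iz * snx;
      for (int t = 0; t < px.size(); ++t) out[base + (px[t] - 1)] = val;
    }
  }
  return out;
}
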