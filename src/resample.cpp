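#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid/affine resampling by trilinear interpolation: out(x) = in(A(x-c) + c)
// with 0-based voxel coordinates; samples outside the volume take `fill`.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dim,
                                  NumericMatrix A, NumericVector center,
                                  double fill) {
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out((R_xlen_t)nx * ny * nz);
  double cx = center[0], cy = center[1], cz = center[2];

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double ux = x - cx, uy = y - cy, uz = z - cz;
        double sx = A(0, 0) * ux + A(0, 1) * uy + A(0, 2) * uz + cx;
        double sy = A(1, 0) * ux + A(1, 1) * uy + A(1, 2) * uz + cy;
        double sz = A(2, 0) * ux + A(2, 1) * uy + A(2, 2) * uz + cz;
        R_xlen_t o = x + (R_xlen_t)nx * y + nxy * z;
        if (sx < 0 || sx > nx - 1 || sy < 0 || sy > ny - 1 ||
            sz < 0 || sz > nz - 1) {
          out[o] = fill;
          continue;
        }
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
            z0 = (int)std::floor(sz);
        int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
            z1 = std::min(z0 + 1, nz - 1);
        double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        auto V = [&](int xi, int yi, int zi) {
          return vol[xi + (R_xlen_t)nx * yi + nxy * zi];
        };
        double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
        double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
        double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
        double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[o] = c0 * (1 - fz) + c1 * fz;
      }
  return out;
}
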