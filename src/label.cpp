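#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected component labeling (degenerates to 4-connectivity when nz = 1).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n);  // zero-initialized
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p / nxy);
      int rem = (int)(p - (R_xlen_t)z * nxy);
      int y = rem / nx;
      int x = rem - y * nx;
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t pn = xx + (R_xlen_t)nx * yy + nxy * zz;
        if (mask[pn] == TRUE && lab[pn] == 0) {
          lab[pn] = next;
          stack.push_back(pn);
        }
      }
    }
  }
  return lab;
}

// For every axial slice, does the foreground form a topologically closed ring?
// Operationalized as: the slice contains foreground AND the in-plane complement
// (4-connectivity) has at least one component with no pixel on the slice border,
// i.e. a hole fully enclosed by foreground.
// [[Rcpp::export]]
LogicalVector cpp_ring_slices(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  LogicalVector ring(nz);
  std::vector<int> lab((size_t)nxy);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    const R_xlen_t off = nxy * z;
    bool any_fg = false;
    for (R_xlen_t i = 0; i < nxy; ++i) {
      lab[(size_t)i] = 0;
      if (mask[off + i] == TRUE) any_fg = true;
    }
    if (!any_fg) {
      ring[z] = FALSE;
      continue;
    }
    int next = 0;
    bool enclosed = false;
    for (R_xlen_t s = 0; s < nxy && !enclosed; ++s) {
      if (mask[off + s] == TRUE || lab[(size_t)s] != 0) continue;
      ++next;
      bool touches = false;
      lab[(size_t)s] = next;
      stack.push_back((int)s);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int y = p / nx, x = p - y * nx;
        if (x == 0 || x == nx - 1 || y == 0 || y == ny - 1) touches = true;
        const int dx[4] = {-1, 1, 0, 0};
        const int dy[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int xx = x + dx[k], yy = y + dy[k];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
          int pn = xx + nx * yy;
          if (mask[off + pn] != TRUE && lab[(size_t)pn] == 0) {
            lab[(size_t)pn] = next;
            stack.push_back(pn);
          }
        }
      }
      if (!touches) enclosed = true;
    }
    ring[z] = enclosed ? TRUE : FALSE;
  }
  return ring;
}
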