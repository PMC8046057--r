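#include "dentomorph.h"
using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1-D squared distance transform.
// INF must stay finite so parabola intersections are well defined.
static const double DM_BIG = 1e15;

static inline double dt_intersect(const std::vector<double>& f, int q, int p) {
  return ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
}

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DM_BIG;  // |s| < DM_BIG for all finite f, so the sentinel terminates the pop loop
  z[1] = DM_BIG;
  for (int q = 1; q < n; ++q) {
    double s = dt_intersect(f, q, v[k]);
    while (s <= z[k]) {
      --k;
      s = dt_intersect(f, q, v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DM_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

void sqedt_internal(const std::vector<char>& feature,
                    int nx, int ny, int nz,
                    bool outside_feature,
                    std::vector<double>& out) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  out.assign(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : DM_BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int zz = 0; zz < nz; ++zz) f[zz] = out[base + nxy * zz];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; ++zz) out[base + nxy * zz] = d[zz];
    }

  if (outside_feature) {
    // nearest outside lattice point is axis-aligned, so the correction is exact
    for (int zz = 0; zz < nz; ++zz)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int dout = std::min(std::min(x + 1, nx - x),
                              std::min(std::min(y + 1, ny - y),
                                       std::min(zz + 1, nz - zz)));
          double d2 = (double)dout * dout;
          R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
          if (d2 < out[i]) out[i] = d2;
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_feature_sqedt(LogicalVector feature, IntegerVector dim,
                                bool outside_feature) {
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> feat(n);
  for (R_xlen_t i = 0; i < n; ++i) feat[i] = feature[i] == TRUE;
  std::vector<double> out;
  sqedt_internal(feat, nx, ny, nz, outside_feature, out);
  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = out[i];
  return res;
}
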