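#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher), one weighted 1-D pass per axis.
// Distances are physical: each axis carries its own spacing. Background
// cost is a large finite sentinel rather than Inf so parabola
// intersections stay well defined.

static const double EDT_INF = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w2) {
  // envelope boundaries must dominate any finite parabola intersection,
  // which can exceed EDT_INF / spacing^2 in magnitude
  const double ZMAX = std::numeric_limits<double>::max();
  int k = 0;
  v[0] = 0;
  z[0] = -ZMAX;
  z[1] = ZMAX;
  for (int q = 1; q < n; q++) {
    double fq = f[q] + w2 * q * q;
    double s = (fq - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = (fq - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZMAX;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt2d_sq")]]
NumericMatrix edt2d_sq(LogicalMatrix feature, double sx, double sy) {
  int nx = feature.nrow(), ny = feature.ncol();
  NumericMatrix d(nx, ny);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++)
      d(i, j) = feature(i, j) ? 0.0 : EDT_INF;

  int nmax = std::max(nx, ny);
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (first index), then y; final value = y-term + x-term
  double wx2 = sx * sx, wy2 = sy * sy;
  for (int j = 0; j < ny; j++) {
    for (int i = 0; i < nx; i++) f[i] = d(i, j);
    dt1d(f, g, v, z, nx, wx2);
    for (int i = 0; i < nx; i++) d(i, j) = g[i];
  }
  for (int i = 0; i < nx; i++) {
    for (int j = 0; j < ny; j++) f[j] = d(i, j);
    dt1d(f, g, v, z, ny, wy2);
    for (int j = 0; j < ny; j++) d(i, j) = g[j];
  }
  return d;
}

// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector feature, IntegerVector dim,
                       double sx, double sy, double sz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; i++) d[i] = feature[i] ? 0.0 : EDT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  double wx2 = sx * sx, wy2 = sy * sy, wz2 = sz * sz;

  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = d[base + i];
      dt1d(f, g, v, z, nx, wx2);
      for (int i = 0; i < nx; i++) d[base + i] = g[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = d[base + (R_xlen_t)j * nx];
      dt1d(f, g, v, z, ny, wy2);
      for (int j = 0; j < ny; j++) d[base + (R_xlen_t)j * nx] = g[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = d[base + (R_xlen_t)k * nx * ny];
      dt1d(f, g, v, z, nz, wz2);
      for (int k = 0; k < nz; k++) d[base + (R_xlen_t)k * nx * ny] = g[k];
    }
  d.attr("dim") = dim;
  return d;
}
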