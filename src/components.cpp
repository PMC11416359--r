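#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labeling by breadth-first flood fill.
// 2-D uses 4- or 8-connectivity; 3-D uses 6-connectivity.

// [[Rcpp::export(name = ".label_components_2d")]]
IntegerMatrix label_components_2d(LogicalMatrix mask, int connectivity) {
  int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  int nn = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      if (!mask(i, j) || lab(i, j) > 0) continue;
      next++;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int t = 0; t < nn; t++) {
          int a = p.first + dx8[t], b = p.second + dy8[t];
          if (a < 0 || a >= nx || b < 0 || b >= ny) continue;
          if (mask(a, b) && lab(a, b) == 0) {
            lab(a, b) = next;
            q.push(std::make_pair(a, b));
          }
        }
      }
    }
  return lab;
}

// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] > 0) continue;
    next++;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t p = q.front();
      q.pop();
      int i = p % nx, j = (p / nx) % ny, k = p / ((R_xlen_t)nx * ny);
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int t = 0; t < 6; t++) {
        int a = i + di[t], b = j + dj[t], c = k + dk[t];
        if (a < 0 || a >= nx || b < 0 || b >= ny || c < 0 || c >= nz) continue;
        R_xlen_t s2 = (R_xlen_t)c * nx * ny + (R_xlen_t)b * nx + a;
        if (mask[s2] && lab[s2] == 0) {
          lab[s2] = next;
          q.push(s2);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
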