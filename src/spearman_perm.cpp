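#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact two-sided permutation p-value for the Spearman coefficient on
// (pre-computed, possibly tied) ranks. All n! index permutations are
// enumerated, so tied ranks carry their correct multiplicity. Feasible
// for n <= 10 (10! = 3,628,800).

// [[Rcpp::export(name = ".spearman_perm_p")]]
double spearman_perm_p(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  if (n < 2 || n > 10) stop("exact permutation p-value requires 2 <= n <= 10");
  double mx = 0, my = 0;
  for (int i = 0; i < n; i++) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  double sxx = 0, syy = 0, sobs = 0;
  for (int i = 0; i < n; i++) {
    sxx += (rx[i] - mx) * (rx[i] - mx);
    syy += (ry[i] - my) * (ry[i] - my);
    sobs += (rx[i] - mx) * (ry[i] - my);
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  double denom = std::sqrt(sxx * syy);
  double robs = std::fabs(sobs / denom);

  std::vector<int> idx(n);
  for (int i = 0; i < n; i++) idx[i] = i;
  long long hits = 0, total = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; i++) s += (rx[i] - mx) * (ry[idx[i]] - my);
    if (std::fabs(s / denom) >= robs - 1e-12) hits++;
    total++;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return (double)hits / (double)total;
}
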