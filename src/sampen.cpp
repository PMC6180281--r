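#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Template-pair counts for sample entropy under the Chebyshev metric with
// strict matching (< r).  Both counts run over start indices 1..M-m so the
// ratio N_{m+1}/N_m is a proper conditional probability and a constant
// series yields exactly 0.  Pairs are enumerated after sorting templates by
// their first coordinate: once the first-coordinate gap reaches r no later
// partner can match, which prunes the O(M^2) scan to the near-diagonal band.
// [[Rcpp::export]]
List sampen_counts(NumericVector y, int m, double r) {
  const int M = y.size();
  const int n_tpl = M - m;  // templates long enough for the (m+1)-extension
  double n_m = 0.0, n_m1 = 0.0;
  if (n_tpl >= 2) {
    std::vector<int> idx(n_tpl);
    for (int i = 0; i < n_tpl; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return y[a] < y[b]; });
    for (int a = 0; a < n_tpl - 1; ++a) {
      const int k = idx[a];
      for (int b = a + 1; b < n_tpl; ++b) {
        const int l = idx[b];
        if (y[l] - y[k] >= r) break;  // sorted: no further partner matches
        bool ok = true;
        for (int d = 1; d < m; ++d) {
          if (std::fabs(y[k + d] - y[l + d]) >= r) { ok = false; break; }
        }
        if (!ok) continue;
        n_m += 1.0;
        if (std::fabs(y[k + m] - y[l + m]) < r) n_m1 += 1.0;
      }
    }
  }
  return List::create(_["n_m"] = n_m, _["n_m1"] = n_m1);
}
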