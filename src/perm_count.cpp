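#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Count permutations of y whose cross-product sum with x falls in either
// tail: sum(x_i * y_perm_i) >= hi or <= lo. Enumerates distinct
// arrangements via std::next_permutation; with tied values each distinct
// arrangement stands for the same number of raw permutations, so the
// returned proportion equals the full-permutation proportion.
// [[Rcpp::export]]
Rcpp::NumericVector perm_crossprod_tail_count(Rcpp::NumericVector x,
                                              Rcpp::NumericVector y,
                                              double lo, double hi) {
  int n = x.size();
  std::vector<double> yp(y.begin(), y.end());
  std::sort(yp.begin(), yp.end());
  double count = 0.0, total = 0.0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i] * yp[i];
    total += 1.0;
    if (s >= hi || s <= lo) count += 1.0;
  } while (std::next_permutation(yp.begin(), yp.end()));
  return Rcpp::NumericVector::create(count, total);
}
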