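#include <Rcpp.h>
using namespace Rcpp;

// Cumulative-cost dynamic program for dynamic time warping.
// `cost` is the pairwise element-cost matrix of the two sequences;
// boundary-matched, step pattern {(1,0),(0,1),(1,1)}, no band constraint.
// [[Rcpp::export(name = ".dtw_dp")]]
double dtw_dp(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n == 0 || m == 0) stop("empty cost matrix");
  std::vector<double> prev(m), cur(m);
  prev[0] = cost(0, 0);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + cost(0, j);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + cost(i, 0);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = best + cost(i, j);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
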