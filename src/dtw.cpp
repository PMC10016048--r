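#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classical DTW with Euclidean local cost, symmetric (match/insert/delete)
// step pattern, no warping window, boundary-anchored, unnormalized cumulative
// cost. Rows are time samples, columns are spatial coordinates.
// [[Rcpp::export]]
double dtw_dist_cpp(NumericMatrix a, NumericMatrix b) {
  const int m = a.nrow(), n = b.nrow(), d = a.ncol();
  if (b.ncol() != d) stop("trajectories must have the same number of coordinates");
  std::vector<double> prev(n + 1, R_PosInf), cur(n + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= n; ++j) {
      double c = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i - 1, k) - b(j - 1, k);
        c += diff * diff;
      }
      c = std::sqrt(c);
      double best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      if (prev[j - 1] < best) best = prev[j - 1];
      cur[j] = c + best;
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), R_PosInf);
  }
  return prev[n];
}
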