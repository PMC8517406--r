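#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Max-statistic permutation null for the cluster-based interaction test.
//
// For each of n_perm random reassignments of the four condition labels
// (preserving group sizes), recomputes the pointwise interaction-contrast
// t series (pooled variance, df = N - 4), forms suprathreshold clusters,
// and returns the largest absolute cluster statistic (0 if no cluster).
// Uses R's RNG so results are reproducible under set.seed().
//
// X: trials x time matrix restricted to the analysis window.
// labels: 1..4 in (LSGS, LDGS, LSGD, LDGD) order.
// threshold: cluster-forming t threshold (> 0).

// [[Rcpp::export]]
NumericVector perm_null_max_cluster(NumericMatrix X, IntegerVector labels,
                                    int n_perm, double threshold) {
  const int n = X.nrow();
  const int T = X.ncol();
  if (labels.size() != n) stop("labels length must match trial count");
  int ng[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    int g = labels[i];
    if (g < 1 || g > 4) stop("labels must be in 1..4");
    ng[g - 1]++;
  }
  for (int g = 0; g < 4; ++g)
    if (ng[g] < 2) stop("need >= 2 trials per condition");
  const int df = n - 4;
  double inv_sum = 0.0;
  for (int g = 0; g < 4; ++g) inv_sum += 1.0 / ng[g];

  std::vector<int> lab(labels.begin(), labels.end());
  NumericVector out(n_perm);

  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle via R RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(lab[i], lab[j]);
    }
    double best = 0.0;
    double run_sum = 0.0;
    int run_sign = 0;
    for (int t = 0; t < T; ++t) {
      double sums[4] = {0, 0, 0, 0};
      double sqs[4] = {0, 0, 0, 0};
      const double *col = &X(0, t);
      for (int i = 0; i < n; ++i) {
        const double v = col[i];
        const int g = lab[i] - 1;
        sums[g] += v;
        sqs[g] += v * v;
      }
      double sse = 0.0;
      for (int g = 0; g < 4; ++g) sse += sqs[g] - sums[g] * sums[g] / ng[g];
      if (sse < 0) sse = 0;  // numerical guard
      const double sp2 = sse / df;
      const double contrast = (sums[3] / ng[3] - sums[2] / ng[2]) -
                              (sums[1] / ng[1] - sums[0] / ng[0]);
      double tval;
      if (sp2 > 0) {
        tval = contrast / std::sqrt(sp2 * inv_sum);
      } else {
        tval = (contrast == 0) ? 0.0
                               : (contrast > 0 ? R_PosInf : R_NegInf);
      }
      int code = (tval > threshold) ? 1 : (tval < -threshold ? -1 : 0);
      if (code == run_sign) {
        if (code != 0) run_sum += tval;
      } else {
        if (run_sign != 0 && std::fabs(run_sum) > best)
          best = std::fabs(run_sum);
        run_sign = code;
        run_sum = (code != 0) ? tval : 0.0;
      }
    }
    if (run_sign != 0 && std::fabs(run_sum) > best)
      best = std::fabs(run_sum);
    out[p] = best;
  }
  return out;
}
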