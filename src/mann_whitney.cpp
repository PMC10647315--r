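#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Two-sided Mann-Whitney p-value per column of m (rows = subjects).
// grp1 marks the first group; pw is the precomputed exact CDF
// P(U <= k) = pw[k] for k = 0..n1*n2, used for untied columns. Tied
// columns fall back to the tie- and continuity-corrected normal
// approximation (as stats::wilcox.test does).
// [[Rcpp::export(name = ".mannWhitneyPCpp")]]
NumericVector mann_whitney_p(NumericMatrix m, LogicalVector grp1,
                             NumericVector pw) {
  int n = m.nrow(), F = m.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) if (grp1[i]) ++n1;
  int n2 = n - n1;
  double mu = n1 * (double)n2 / 2.0;
  NumericVector out(F);
  std::vector<int> ord(n);
  std::vector<double> r(n);
  for (int k = 0; k < F; ++k) {
    NumericMatrix::Column x = m(_, k);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    // average ranks, track ties
    bool tied = false;
    double tiecorr = 0.0;
    int i = 0;
    while (i < n) {
      int j = i;
      while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
      double avg = (i + j) / 2.0 + 1.0;
      for (int t = i; t <= j; ++t) r[ord[t]] = avg;
      int cnt = j - i + 1;
      if (cnt > 1) {
        tied = true;
        tiecorr += (double)cnt * cnt * cnt - cnt;
      }
      i = j + 1;
    }
    double rsum = 0.0;
    for (int t = 0; t < n; ++t) if (grp1[t]) rsum += r[t];
    double u = rsum - n1 * (n1 + 1.0) / 2.0;
    double p;
    if (!tied) {
      int ui = (int)(u + 0.5);
      if (u > mu)
        p = 2.0 * (1.0 - pw[ui - 1]);
      else
        p = 2.0 * pw[ui];
      if (p > 1.0) p = 1.0;
    } else {
      double sig2 = (n1 * (double)n2 / 12.0) *
        ((n + 1.0) - tiecorr / ((double)n * (n - 1.0)));
      if (sig2 <= 0) { out[k] = 1.0; continue; }
      double z = u - mu;
      if (z > 0) z -= 0.5; else if (z < 0) z += 0.5;  // continuity
      p = 2.0 * R::pnorm(-std::fabs(z) / std::sqrt(sig2), 0.0, 1.0, 1, 0);
    }
    out[k] = p;
  }
  return out;
}
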