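#include <Rcpp.h>
using namespace Rcpp;

// Per-feature leave-one-out accuracy of a single-covariate logistic
// regression, fitted by Newton iterations with coefficients clamped to
// +/- cap (the bounded-coefficient fallback under perfect separation:
// predictions saturate instead of diverging). Called once per outer LOOCV
// fold of the evaluation suite, hence compiled.
// [[Rcpp::export(name = ".logisticLoocvAccuracyCpp")]]
NumericVector logistic_loocv_accuracy(NumericMatrix X, IntegerVector y,
                                      double cap, int maxit, double tol) {
  int n = X.nrow(), F = X.ncol();
  NumericVector acc(F);
  for (int k = 0; k < F; ++k) {
    int ncorrect = 0;
    for (int j = 0; j < n; ++j) {
      double b0 = 0.0, b1 = 0.0;
      for (int it = 0; it < maxit; ++it) {
        double g0 = 0, g1 = 0, h00 = 0, h01 = 0, h11 = 0;
        for (int i = 0; i < n; ++i) {
          if (i == j) continue;
          double x = X(i, k);
          double p = 1.0 / (1.0 + std::exp(-(b0 + b1 * x)));
          double w = p * (1.0 - p);
          if (w < 1e-10) w = 1e-10;
          double r = y[i] - p;
          g0 += r;
          g1 += r * x;
          h00 += w;
          h01 += w * x;
          h11 += w * x * x;
        }
        double det = h00 * h11 - h01 * h01;
        if (det < 1e-12) det = 1e-12;
        double d0 = (h11 * g0 - h01 * g1) / det;
        double d1 = (h00 * g1 - h01 * g0) / det;
        double p0 = b0, p1 = b1;
        b0 += d0;
        b1 += d1;
        if (b0 > cap) b0 = cap;
        if (b0 < -cap) b0 = -cap;
        if (b1 > cap) b1 = cap;
        if (b1 < -cap) b1 = -cap;
        // post-clamp change: clamped (separated) fits stop immediately
        if (std::fabs(b0 - p0) < tol && std::fabs(b1 - p1) < tol) break;
      }
      double ph = 1.0 / (1.0 + std::exp(-(b0 + b1 * X(j, k))));
      bool pred = ph > 0.5;
      if (pred == (y[j] == 1)) ++ncorrect;
    }
    acc[k] = static_cast<double>(ncorrect) / n;
  }
  return acc;
}
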