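#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM:
//   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// with the bias absorbed as an augmented constant feature of value `bias_scale`
// (so the bias is regularized, as in liblinear's -B option). Deterministic
// given the epoch permutation order supplied from R.
//
// `xt` holds one training example per COLUMN (p x n), so the inner loops
// stream contiguous memory.
//
// [[Rcpp::export]]
List dcd_svm_fit(NumericMatrix xt, NumericVector y, double cost,
                 double bias_scale, IntegerMatrix order, double tol,
                 int max_epochs) {
  const int p = xt.nrow(), n = xt.ncol();
  std::vector<double> w(p + 1, 0.0), alpha(n, 0.0), qii(n);
  const double *X = REAL(xt);
  for (int i = 0; i < n; ++i) {
    const double *xi = X + (size_t)i * p;
    double s = bias_scale * bias_scale;
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
  int epoch = 0;
  double max_pg = R_PosInf;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    max_pg = 0.0;
    const int ocol = epoch % order.ncol();
    for (int k = 0; k < n; ++k) {
      const int i = order(k, ocol) - 1;
      if (qii[i] <= 0) continue;
      const double *xi = X + (size_t)i * p;
      double wx = w[p] * bias_scale;
      for (int j = 0; j < p; ++j) wx += w[j] * xi[j];
      const double g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      if (alpha[i] >= cost && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > cost) a_new = cost;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * xi[j];
          w[p] += d * bias_scale;
        }
      }
    }
    if (max_pg < tol) break;
  }
  NumericVector weights(p);
  for (int j = 0; j < p; ++j) weights[j] = w[j];
  return List::create(_["weights"] = weights,
                      _["bias"] = w[p] * bias_scale,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch + 1,
                      _["max_violation"] = max_pg,
                      _["converged"] = max_pg < tol);
}
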