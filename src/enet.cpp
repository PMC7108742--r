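#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic-net penalized weighted least
// squares problem
//   min_{b0, beta}  (1/(2n)) sum_i w_i (z_i - b0 - x_i' beta)^2
//                   + lambda * ( alpha * ||beta||_1 + (1-alpha)/2 ||beta||_2^2 )
// Columns of X are expected pre-standardized; the intercept is unpenalized.
// beta / b0 are warm starts and are updated in place via the return value.
// [[Rcpp::export(name = ".enet_wls_cpp")]]
List enet_wls_cpp(NumericMatrix X, NumericVector z, NumericVector w,
                  double lambda, double alpha,
                  NumericVector beta_init, double b0_init,
                  double tol, int maxit) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  double b0 = b0_init;

  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];

  // weighted column second moments
  std::vector<double> xwx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
    xwx[j] = s / n;
  }

  // residual r = z - b0 - X beta
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) {
    double eta = b0;
    for (int j = 0; j < p; ++j)
      if (beta[j] != 0.0) eta += X(i, j) * beta[j];
    r[i] = z[i] - eta;
  }

  double l1 = lambda * alpha, l2 = lambda * (1.0 - alpha);

  auto update_b0 = [&]() -> double {
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * r[i];
    double db0 = num / wsum;
    if (db0 != 0.0) {
      b0 += db0;
      for (int i = 0; i < n; ++i) r[i] -= db0;
    }
    return std::fabs(db0);
  };
  auto update_coord = [&](int j) -> double {
    if (xwx[j] <= 0.0) return 0.0;
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += w[i] * X(i, j) * r[i];
    g = g / n + xwx[j] * beta[j];
    double bj;
    if (g > l1) bj = (g - l1) / (xwx[j] + l2);
    else if (g < -l1) bj = (g + l1) / (xwx[j] + l2);
    else bj = 0.0;
    double diff = bj - beta[j];
    if (diff != 0.0) {
      beta[j] = bj;
      for (int i = 0; i < n; ++i) r[i] -= diff * X(i, j);
    }
    return std::fabs(diff);
  };

  // full passes establish the active set; inner cycles over the nonzero
  // coordinates do the bulk of the work (glmnet-style active-set descent)
  int it = 0;
  while (it < maxit) {
    double maxdelta = update_b0();
    for (int j = 0; j < p; ++j) {
      double d = update_coord(j);
      if (d > maxdelta) maxdelta = d;
    }
    ++it;
    if (maxdelta < tol) break;
    std::vector<int> active;
    active.reserve(p);
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (it < maxit) {
      double md = update_b0();
      for (int j : active) {
        double d = update_coord(j);
        if (d > md) md = d;
      }
      ++it;
      if (md < tol) break;
    }
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["b0"] = b0, _["iterations"] = it + 1);
}
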