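#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for L1-penalised logistic regression along a
// decreasing lambda path with warm starts.
//
// Objective per lambda: (1/n) sum_i [log(1+exp(eta_i)) - y_i eta_i]
//                       + lambda * sum_j |beta_j|,
// eta = b0 + X beta, X standardized by the caller, intercept unpenalised.
// The outer loop is an IRLS quadratic approximation; the inner loop is
// coordinate descent on the penalised weighted least squares problem.
//
// Returns intercepts, the coefficient matrix (p x nlambda), the deviance
// per lambda and a separation flag (|eta| blowing up at small lambda).
// [[Rcpp::export]]
List lasso_logistic_cd(NumericMatrix X, NumericVector y, NumericVector lambda,
                       double tol = 1e-10, int maxit_outer = 50,
                       int maxit_inner = 2000) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  NumericMatrix beta(p, nlam);
  NumericVector b0(nlam), deviance(nlam);
  LogicalVector separated(nlam);

  std::vector<double> bj(p, 0.0);
  double ybar = mean(y);
  double intercept = std::log(ybar / (1.0 - ybar));
  std::vector<double> eta(n, intercept);

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    double dev_prev = R_PosInf;
    bool sep = false;

    for (int outer = 0; outer < maxit_outer; ++outer) {
      // IRLS working response and weights at current eta
      std::vector<double> w(n), z(n);
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double pi = 1.0 / (1.0 + std::exp(-eta[i]));
        if (pi < 1e-8) pi = 1e-8;
        if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;
        double wi = pi * (1.0 - pi);
        if (wi < 1e-6) wi = 1e-6;
        w[i] = wi;
        z[i] = eta[i] + (y[i] - pi) / wi;
        dev += -2.0 * (y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi));
      }
      if (std::fabs(dev_prev - dev) < 1e-10 * (std::fabs(dev) + 1.0) && outer > 0)
        break;
      dev_prev = dev;

      // residual r = z - b0 - X beta
      std::vector<double> r(n);
      for (int i = 0; i < n; ++i) {
        double xb = intercept;
        for (int j = 0; j < p; ++j) xb += X(i, j) * bj[j];
        r[i] = z[i] - xb;
      }

      for (int inner = 0; inner < maxit_inner; ++inner) {
        double maxdel = 0.0;
        for (int j = 0; j < p; ++j) {
          double num = 0.0, den = 0.0;
          for (int i = 0; i < n; ++i) {
            num += w[i] * X(i, j) * (r[i] + X(i, j) * bj[j]);
            den += w[i] * X(i, j) * X(i, j);
          }
          num /= n; den /= n;
          double bnew = soft(num, lam) / den;
          double del = bnew - bj[j];
          if (del != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= X(i, j) * del;
            bj[j] = bnew;
            double ad = std::fabs(del);
            if (ad > maxdel) maxdel = ad;
          }
        }
        // intercept
        double sw = 0.0, swr = 0.0;
        for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * r[i]; }
        double d0 = swr / sw;
        if (d0 != 0.0) {
          intercept += d0;
          for (int i = 0; i < n; ++i) r[i] -= d0;
          if (std::fabs(d0) > maxdel) maxdel = std::fabs(d0);
        }
        if (maxdel < tol) break;
      }

      for (int i = 0; i < n; ++i) {
        double xb = intercept;
        for (int j = 0; j < p; ++j) xb += X(i, j) * bj[j];
        eta[i] = xb;
        if (std::fabs(xb) > 30.0) sep = true;
      }
      if (sep) break;
    }

    double dev = 0.0;
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta[i]));
      if (pi < 1e-10) pi = 1e-10;
      if (pi > 1.0 - 1e-10) pi = 1.0 - 1e-10;
      dev += -2.0 * (y[i] * std::log(pi) + (1.0 - y[i]) * std::log(1.0 - pi));
    }
    b0[l] = intercept;
    deviance[l] = dev;
    separated[l] = sep;
    for (int j = 0; j < p; ++j) beta(j, l) = bj[j];
    if (sep) {
      // truncate: keep current solution for this lambda, stop descending
      for (int l2 = l + 1; l2 < nlam; ++l2) separated[l2] = true;
      break;
    }
  }

  return List::create(_["b0"] = b0, _["beta"] = beta,
                      _["deviance"] = deviance, _["separated"] = separated);
}
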