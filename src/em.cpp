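#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Univariate Gaussian-mixture EM inner loop. Responsibilities are computed in
// log space (log-sum-exp) so well-separated components stay stable. The
// log-likelihood is non-decreasing across iterations by EM construction; the
// full trace is returned so callers can verify monotonicity.
//
// variance_family: 0 = unequal (component-specific), 1 = equal (shared).
// [[Rcpp::export(name = ".em_run_cpp")]]
List em_run_cpp(NumericVector values, NumericVector w0, NumericVector mu0,
                NumericVector s20, int variance_family, int max_iter,
                double tol, double var_floor) {
  const int n = values.size();
  const int K = w0.size();
  if (K > 64) stop("more than 64 components not supported");
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> s2(s20.begin(), s20.end());
  for (int k = 0; k < K; ++k) s2[k] = std::max(s2[k], var_floor);
  if (variance_family == 1) {
    double m = 0.0;
    for (int k = 0; k < K; ++k) m += s2[k];
    m /= K;
    for (int k = 0; k < K; ++k) s2[k] = m;
  }

  std::vector<double> resp(n * K);
  std::vector<double> logL_trace;
  logL_trace.reserve(64);
  const double LOG2PI = std::log(2.0 * M_PI);
  double logL_old = R_NegInf, logL = R_NegInf;
  bool converged = false;
  int iter = 0;

  auto estep = [&](bool store_resp) -> double {
    double total = 0.0;
    double lc[64], inv2[64];
    for (int k = 0; k < K; ++k) {
      lc[k] = std::log(w[k]) - 0.5 * (LOG2PI + std::log(s2[k]));
      inv2[k] = 0.5 / s2[k];
    }
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      double lp[64], e[64];
      for (int k = 0; k < K; ++k) {
        double d = values[i] - mu[k];
        lp[k] = lc[k] - d * d * inv2[k];
        if (lp[k] > m) m = lp[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        e[k] = std::exp(lp[k] - m);
        s += e[k];
      }
      total += m + std::log(s);
      if (store_resp) {
        double inv_s = 1.0 / s;
        for (int k = 0; k < K; ++k) resp[i + n * k] = e[k] * inv_s;
      }
    }
    return total;
  };

  while (iter < max_iter) {
    ++iter;
    logL = estep(true);
    logL_trace.push_back(logL);
    // M-step
    double pooled = 0.0;
    for (int k = 0; k < K; ++k) {
      double nk = 0.0, sum = 0.0;
      for (int i = 0; i < n; ++i) {
        nk += resp[i + n * k];
        sum += resp[i + n * k] * values[i];
      }
      if (nk < 1e-300) nk = 1e-300;
      w[k] = nk / n;
      mu[k] = sum / nk;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = values[i] - mu[k];
        ss += resp[i + n * k] * d * d;
      }
      if (variance_family == 1) {
        pooled += ss;
      } else {
        s2[k] = std::max(ss / nk, var_floor);
      }
    }
    if (variance_family == 1) {
      double v = std::max(pooled / n, var_floor);
      for (int k = 0; k < K; ++k) s2[k] = v;
    }
    if (R_FINITE(logL_old) &&
        std::fabs(logL - logL_old) <= tol * (std::fabs(logL_old) + 1e-12)) {
      converged = true;
      break;
    }
    logL_old = logL;
  }
  // final logL under the last M-step parameters
  logL = estep(false);
  logL_trace.push_back(logL);

  return List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["means"] = NumericVector(mu.begin(), mu.end()),
    _["variances"] = NumericVector(s2.begin(), s2.end()),
    _["logL"] = logL,
    _["converged"] = converged,
    _["n_iter"] = iter,
    _["logL_trace"] = NumericVector(logL_trace.begin(), logL_trace.end())
  );
}
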