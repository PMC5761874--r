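#include <Rcpp.h>
using namespace Rcpp;

// ARMA(p,q) mean filter + GARCH(1,1) variance filter, Gaussian quasi-likelihood.
//
// Mean recursion:   mu_t = alpha + sum_i beta_i z_{t-i} - sum_j theta_j eps_{t-j}
// Variance filter:  sig2_t = omega + phi * eps_{t-1}^2 + psi * sig2_{t-1}
//
// The first max(p, q) observations are conditioned upon (eps = 0, mu = z);
// sig2 is initialised at the sample variance of the mean-filter residuals and
// the log-likelihood is accumulated from t = max(p, q) + 1 onward (0-based
// index m), so presample conventions do not contribute pseudo-information.
// [[Rcpp::export]]
List arma_garch_filter_cpp(NumericVector z,
                           double alpha,
                           NumericVector beta,
                           NumericVector theta,
                           double omega,
                           double phi,
                           double psi) {
  const int T = z.size();
  const int p = beta.size();
  const int q = theta.size();
  const int m = std::max(p, q);

  NumericVector mu(T), eps(T), sig2(T);

  for (int t = 0; t < T; ++t) {
    if (t < m) {
      mu[t] = z[t];
      eps[t] = 0.0;
      continue;
    }
    double mt = alpha;
    for (int i = 0; i < p; ++i) mt += beta[i] * z[t - 1 - i];
    for (int j = 0; j < q; ++j) mt -= theta[j] * eps[t - 1 - j];
    mu[t] = mt;
    eps[t] = z[t] - mt;
  }

  // presample variance: sample variance of the residuals actually filtered
  double s = 0.0, ss = 0.0;
  int n = 0;
  for (int t = m; t < T; ++t) { s += eps[t]; ss += eps[t] * eps[t]; ++n; }
  double v0 = (n > 1) ? (ss - s * s / n) / (n - 1) : omega;
  if (!(v0 > 0.0)) v0 = omega / std::max(1e-12, 1.0 - phi - psi);

  double ll = 0.0;
  const double l2pi = std::log(2.0 * M_PI);
  double prev = v0;
  for (int t = 0; t < T; ++t) {
    double v = (t == 0) ? v0 : omega + phi * eps[t - 1] * eps[t - 1] + psi * prev;
    if (!(v > 0.0) || !std::isfinite(v)) {
      return List::create(_["ok"] = false, _["loglik"] = R_NegInf);
    }
    sig2[t] = v;
    prev = v;
    if (t >= m) ll += -0.5 * (l2pi + std::log(v) + eps[t] * eps[t] / v);
  }

  return List::create(_["ok"] = true,
                      _["mu"] = mu,
                      _["eps"] = eps,
                      _["sig2"] = sig2,
                      _["loglik"] = ll,
                      _["m"] = m);
}

// DCC(1,1) correlation filter for a bivariate standardized-residual matrix.
//
//   Q_t = (1 - eta1 - eta2) * Xi + eta1 * u_{t-1} u_{t-1}' + eta2 * Q_{t-1}
//   R_t = diag(Q_t)^{-1/2} Q_t diag(Q_t)^{-1/2},   Q_1 = Xi
//
// Returns the off-diagonal correlation trajectory rho_t, the Q component
// series (q11, q12, q22) and the Gaussian correlation log-likelihood
//   -1/2 * sum_t [ log|R_t| + u_t' R_t^{-1} u_t - u_t' u_t ].
// [[Rcpp::export]]
List dcc_filter_cpp(NumericMatrix u, double eta1, double eta2,
                    double xi11, double xi12, double xi22) {
  const int T = u.nrow();
  NumericVector rho(T), q11s(T), q12s(T), q22s(T);

  double q11 = xi11, q12 = xi12, q22 = xi22;
  double ll = 0.0;
  const double w = 1.0 - eta1 - eta2;

  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      const double u1 = u(t - 1, 0), u2 = u(t - 1, 1);
      q11 = w * xi11 + eta1 * u1 * u1 + eta2 * q11;
      q12 = w * xi12 + eta1 * u1 * u2 + eta2 * q12;
      q22 = w * xi22 + eta1 * u2 * u2 + eta2 * q22;
    }
    if (!(q11 > 0.0) || !(q22 > 0.0)) {
      return List::create(_["ok"] = false, _["loglik"] = R_NegInf);
    }
    double r = q12 / std::sqrt(q11 * q22);
    if (r > 1.0) r = 1.0;
    if (r < -1.0) r = -1.0;
    rho[t] = r;
    q11s[t] = q11; q12s[t] = q12; q22s[t] = q22;

    const double det = 1.0 - r * r;
    if (!(det > 0.0)) {
      return List::create(_["ok"] = false, _["loglik"] = R_NegInf);
    }
    const double u1 = u(t, 0), u2 = u(t, 1);
    const double quad = (u1 * u1 - 2.0 * r * u1 * u2 + u2 * u2) / det;
    ll += -0.5 * (std::log(det) + quad - (u1 * u1 + u2 * u2));
  }

  return List::create(_["ok"] = true,
                      _["rho"] = rho,
                      _["q11"] = q11s, _["q12"] = q12s, _["q22"] = q22s,
                      _["loglik"] = ll);
}
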