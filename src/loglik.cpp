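#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli action likelihood and Beta success-rate likelihood for a
// cohort of compiled BART sessions.  A compiled session (see
// compile_session() on the R side) carries the concatenated action
// stream y with per-action trial (kk) and occasion (jj) indices, the
// clamped cumulative success rates ck and the indices ck_use where they
// are defined.

static const double THETA_EPS = 1e-12;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Per-subject sum over observed actions of the Bernoulli log-density,
// with theta from the belief -> burst-probability -> pump-target ->
// logistic-response chain.  log(1 - p*) == log(mu), which keeps the
// pump-target computation stable for mu near 1.
// [[Rcpp::export]]
NumericVector cohort_action_loglik_cpp(List compiled,
                                       NumericVector gamma,
                                       NumericVector beta,
                                       NumericVector alpha0,
                                       NumericVector alpha1) {
  const int S = compiled.size();
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    List cs = compiled[s];
    IntegerVector y = cs["y"], kk = cs["kk"], jj = cs["jj"];
    const int K = as<int>(cs["K"]);
    const double g = gamma[s], b = beta[s], a0 = alpha0[s], a1 = alpha1[s];

    // per-trial pump target omega_k
    std::vector<double> omega(K + 1);
    for (int k = 1; k <= K; ++k) {
      double mu = inv_logit(a0 + a1 * k);      // success-rate belief
      double logmu = std::log(mu);             // = log(1 - p*_k)
      omega[k] = (logmu == 0.0) ? R_PosInf : -g / logmu;
    }

    double ll = 0.0;
    const int n = y.size();
    for (int i = 0; i < n; ++i) {
      double theta = inv_logit(-b * (jj[i] - omega[kk[i]]));
      if (theta < THETA_EPS) theta = THETA_EPS;
      if (theta > 1.0 - THETA_EPS) theta = 1.0 - THETA_EPS;
      ll += (y[i] == 1) ? std::log(theta) : std::log1p(-theta);
    }
    out[s] = ll;
  }
  return out;
}

// Beta log-likelihood of the clamped cumulative success rates under the
// mean/concentration parameterisation: C_k ~ Beta(mu_k*sa, (1-mu_k)*sa).
// [[Rcpp::export]]
NumericVector cohort_csr_loglik_cpp(List compiled,
                                    NumericVector alpha0,
                                    NumericVector alpha1,
                                    double sigma_alpha) {
  const int S = compiled.size();
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    List cs = compiled[s];
    NumericVector ck = cs["ck"];
    IntegerVector use = cs["ck_use"];
    const double a0 = alpha0[s], a1 = alpha1[s];
    double ll = 0.0;
    for (int i = 0; i < use.size(); ++i) {
      const int k = use[i];                    // 1-based trial index
      double mu = inv_logit(a0 + a1 * k);
      double sh1 = mu * sigma_alpha, sh2 = (1.0 - mu) * sigma_alpha;
      ll += R::dbeta(ck[k - 1], sh1, sh2, 1);
    }
    out[s] = ll;
  }
  return out;
}
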