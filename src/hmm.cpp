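#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Scaled forward-backward for a 2-state HMM with Poisson emissions.
// Returns log-likelihood, per-bin posteriors (gamma), expected transition
// counts (xi summed over time), and expected initial-state occupancy.
static void forward_backward(const IntegerVector& x,
                             const NumericVector& lambda,
                             const NumericMatrix& trans,
                             const NumericVector& init,
                             NumericMatrix& gamma,
                             NumericMatrix& xi_sum,
                             double& loglik) {
  const int T = x.size(), K = lambda.size();
  NumericMatrix B(T, K);      // emission probabilities (scaled per row)
  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    std::vector<double> lp(K);
    for (int k = 0; k < K; ++k) {
      double lam = std::max(lambda[k], 1e-10);
      lp[k] = R::dpois(x[t], lam, 1);
      if (lp[k] > mx) mx = lp[k];
    }
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(lp[k] - mx);
  }
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);         // per-step scaling factors
  loglik = 0.0;
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) s = DBL_MIN;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    if (s <= 0) s = DBL_MIN;
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  // log-likelihood must add back the per-row emission scaling dropped above;
  // that scaling cancels in gamma/xi but not in the likelihood, so recompute
  // it exactly.
  // c[t] already includes B scaled by exp(-mx_t); add the mx terms.
  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double lam = std::max(lambda[k], 1e-10);
      double lp = R::dpois(x[t], lam, 1);
      if (lp > mx) mx = lp;
    }
    loglik += std::log(c[t]) + mx;
  }
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += trans(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }
  // posteriors and expected transitions
  for (int t = 0; t < T; ++t) {
    double s2 = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s2 += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s2;
  }
  std::fill(xi_sum.begin(), xi_sum.end(), 0.0);
  for (int t = 0; t < T - 1; ++t) {
    double denom = 0.0;
    double tmp[2][2];
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        tmp[j][k] = alpha(t, j) * trans(j, k) * B(t + 1, k) * beta(t + 1, k);
        denom += tmp[j][k];
      }
    if (denom <= 0) continue;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += tmp[j][k] / denom;
  }
}

// [[Rcpp::export]]
List hmm_posteriors_cpp(IntegerVector x, NumericVector lambda,
                        NumericMatrix trans, NumericVector init) {
  const int T = x.size(), K = lambda.size();
  NumericMatrix gamma(T, K), xi_sum(K, K);
  double ll = 0.0;
  forward_backward(x, lambda, trans, init, gamma, xi_sum, ll);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// [[Rcpp::export]]
List hmm_baum_welch_cpp(IntegerVector x, NumericVector lambda0,
                        NumericMatrix trans0, NumericVector init0,
                        double tol, int max_iter) {
  const int T = x.size(), K = lambda0.size();
  NumericVector lambda = clone(lambda0), init = clone(init0);
  NumericMatrix trans = clone(trans0);
  NumericMatrix gamma(T, K), xi_sum(K, K);
  std::vector<double> trace;
  double ll = R_NegInf, ll_prev = R_NegInf;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    forward_backward(x, lambda, trans, init, gamma, xi_sum, ll);
    trace.push_back(ll);
    if (it > 0 && std::fabs(ll - ll_prev) <=
        tol * (std::fabs(ll_prev) + 1e-12)) { converged = true; break; }
    ll_prev = ll;
    // M-step
    for (int k = 0; k < K; ++k) {
      double num = 0.0, den = 0.0;
      for (int t = 0; t < T; ++t) { num += gamma(t, k) * x[t]; den += gamma(t, k); }
      lambda[k] = den > 0 ? num / den : lambda[k];
      init[k] = gamma(0, k);
      double row = 0.0;
      for (int j = 0; j < K; ++j) row += xi_sum(k, j);
      if (row > 0)
        for (int j = 0; j < K; ++j) trans(k, j) = xi_sum(k, j) / row;
    }
  }
  return List::create(_["lambda"] = lambda, _["trans"] = trans,
                      _["init"] = init, _["loglik_trace"] = wrap(trace),
                      _["converged"] = converged);
}
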