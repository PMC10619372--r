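#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scaled forward-algorithm log-likelihood of a discrete symbol sequence
// (0-based symbols). Empty sequence -> 0 (empty-product convention).
// [[Rcpp::export]]
double hmm_forward_cpp(IntegerVector obs, NumericVector prior,
                       NumericMatrix trans, NumericMatrix emis) {
  int T = obs.size(), K = prior.size(), S = emis.ncol();
  if (T == 0) return 0.0;
  for (int t = 0; t < T; ++t)
    if (obs[t] < 0 || obs[t] >= S) stop("symbol outside the emission alphabet");
  std::vector<double> a(K), a2(K);
  double ll = 0.0;
  double c = 0.0;
  for (int k = 0; k < K; ++k) { a[k] = prior[k] * emis(k, obs[0]); c += a[k]; }
  if (c <= 0) return R_NegInf;
  for (int k = 0; k < K; ++k) a[k] /= c;
  ll += std::log(c);
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int l = 0; l < K; ++l) s += a[l] * trans(l, k);
      a2[k] = s * emis(k, obs[t]);
      c += a2[k];
    }
    if (c <= 0) return R_NegInf;
    for (int k = 0; k < K; ++k) a[k] = a2[k] / c;
    ll += std::log(c);
  }
  return ll;
}

// Baum-Welch EM for a discrete-emission HMM with forward/backward scaling.
// Returns the re-estimated parameters and the per-iteration log-likelihood
// trace (evaluated at the parameters entering each iteration, so the trace is
// monotone non-decreasing).
// [[Rcpp::export]]
List hmm_baum_welch_cpp(IntegerVector obs, int n_states, int n_symbols,
                        NumericVector prior0, NumericMatrix trans0,
                        NumericMatrix emis0, double tol, int max_iter) {
  int T = obs.size(), K = n_states, S = n_symbols;
  if (T < 2) stop("sequence too short for Baum-Welch");
  NumericVector prior = clone(prior0);
  NumericMatrix trans = clone(trans0), emis = clone(emis0);
  std::vector<double> alpha((size_t)T * K), beta((size_t)T * K), cvec(T);
  std::vector<double> ll_trace;
  double prev_ll = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    // forward (scaled)
    double c = 0.0;
    for (int k = 0; k < K; ++k) { alpha[k] = prior[k] * emis(k, obs[0]); c += alpha[k]; }
    if (c <= 0) stop("zero forward probability (degenerate emission)");
    for (int k = 0; k < K; ++k) alpha[k] /= c;
    cvec[0] = c;
    for (int t = 1; t < T; ++t) {
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int l = 0; l < K; ++l) s += alpha[(size_t)(t - 1) * K + l] * trans(l, k);
        double v = s * emis(k, obs[t]);
        alpha[(size_t)t * K + k] = v;
        c += v;
      }
      if (c <= 0) stop("zero forward probability (degenerate emission)");
      for (int k = 0; k < K; ++k) alpha[(size_t)t * K + k] /= c;
      cvec[t] = c;
    }
    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(cvec[t]);
    ll_trace.push_back(ll);
    if (iter > 0 && ll - prev_ll < tol) { prev_ll = ll; break; }
    prev_ll = ll;

    // backward (scaled by the same c_t)
    for (int k = 0; k < K; ++k) beta[(size_t)(T - 1) * K + k] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int l = 0; l < K; ++l)
          s += trans(k, l) * emis(l, obs[t + 1]) * beta[(size_t)(t + 1) * K + l];
        beta[(size_t)t * K + k] = s / cvec[t + 1];
      }
    }

    // expected counts
    NumericVector pr_new(K);
    NumericMatrix tr_new(K, K), em_new(K, S);
    std::vector<double> gsum(K, 0.0);
    for (int t = 0; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double g = alpha[(size_t)t * K + k] * beta[(size_t)t * K + k];
        if (t == 0) pr_new[k] = g;
        em_new(k, obs[t]) += g;
        gsum[k] += g;
      }
    }
    for (int t = 0; t < T - 1; ++t) {
      for (int k = 0; k < K; ++k) {
        double ak = alpha[(size_t)t * K + k];
        if (ak == 0.0) continue;
        for (int l = 0; l < K; ++l) {
          tr_new(k, l) += ak * trans(k, l) * emis(l, obs[t + 1]) *
                          beta[(size_t)(t + 1) * K + l] / cvec[t + 1];
        }
      }
    }
    // normalize (uniform fallback for unvisited states)
    double psum = 0.0;
    for (int k = 0; k < K; ++k) psum += pr_new[k];
    for (int k = 0; k < K; ++k) prior[k] = psum > 0 ? pr_new[k] / psum : 1.0 / K;
    for (int k = 0; k < K; ++k) {
      double rs = 0.0;
      for (int l = 0; l < K; ++l) rs += tr_new(k, l);
      for (int l = 0; l < K; ++l) trans(k, l) = rs > 0 ? tr_new(k, l) / rs : 1.0 / K;
      double es = gsum[k];
      for (int s2 = 0; s2 < S; ++s2) emis(k, s2) = es > 0 ? em_new(k, s2) / es : 1.0 / S;
    }
  }
  return List::create(_["prior"] = prior, _["trans"] = trans, _["emis"] = emis,
                      _["ll_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["loglik"] = prev_ll);
}
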