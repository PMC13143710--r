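#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-time HMM with precomputed
// per-timepoint log emission densities. logB is T x K. Returns the exact
// log-likelihood, posterior state probabilities gamma (T x K) and the
// summed two-slice marginals xi_sum (K x K) needed by the Baum-Welch M-step.
//
// Scaling: at each t the joint alpha is normalised to sum 1; the log of the
// normaliser accumulates into the log-likelihood. Emission densities are
// exponentiated after subtracting the per-row max of logB, which keeps the
// recursion in a safe floating range without changing the posteriors.
// [[Rcpp::export]]
List cpp_forward_backward(NumericVector log_init, NumericMatrix log_trans,
                          NumericMatrix logB) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K);           // shifted emission likelihoods
  NumericVector bshift(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    if (!R_finite(m)) stop("all emission densities underflowed at timepoint %d", t + 1);
    bshift[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(log_trans(i, j));

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector cnorm(T);
  double ll = 0.0;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = std::exp(log_init[k]) * B(0, k);
    s += alpha(0, k);
  }
  if (s <= 0.0 || !R_finite(s))
    stop("zero total emission likelihood at timepoint 1 (numerical underflow)");
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  cnorm[0] = s;
  ll += std::log(s) + bshift[0];
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0 || !R_finite(s))
      stop("zero total emission likelihood at timepoint %d (numerical underflow)", t + 1);
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
    cnorm[t] = s;
    ll += std::log(s) + bshift[t];
  }

  // backward (scaled by the forward normalisers)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / cnorm[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(t, i);
      for (int j = 0; j < K; ++j)
        xi(i, j) += ai * A(i, j) * B(t + 1, j) * beta(t + 1, j) / cnorm[t + 1];
    }
  }

  return List::create(_["log_lik"] = ll, _["gamma"] = gamma, _["xi_sum"] = xi);
}

// Viterbi decoding in log space. Ties are broken toward the lower state
// index (strict improvement required to switch), making the path
// deterministic for fully symmetric models. Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericVector log_init, NumericMatrix log_trans,
                          NumericMatrix logB) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = log_init[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + log_trans(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + log_trans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  if (!R_finite(best)) stop("Viterbi path has -Inf log-probability (emission underflow)");
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
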