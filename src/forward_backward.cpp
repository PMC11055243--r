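#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a Gaussian-emission HMM.
// Returns log-likelihood, posterior matrix gamma (T x K), the summed
// pairwise posteriors xi (K x K, summed over t = 1..T-1) and gamma at t = 1.
// Scaling constants c_t normalise the forward variable so that the
// log-likelihood is the sum of log c_t; the backward recursion reuses the
// same constants, which makes alpha_t * beta_t directly proportional to the
// state posterior.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericVector start, NumericMatrix trans,
            NumericVector means, NumericVector sds, NumericVector x) {
  const int K = start.size();
  const int T = x.size();
  NumericMatrix B(T, K);   // emission densities
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      B(t, k) = R::dnorm(x[t], means[k], sds[k], 0);

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = start[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("forward recursion underflowed at t = 1 (observation in the tail of every state)");
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
    if (s <= 0.0) stop("forward recursion underflowed at t = %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += trans(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * trans(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);

  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi, _["gamma1"] = gamma(0, _));
}
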