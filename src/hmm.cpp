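#include <Rcpp.h>
using namespace Rcpp;

static inline double lgauss(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// Viterbi path for a 2-state Gaussian HMM. States: 0 = linker,
// 1 = nucleosome. Ties are broken toward the linker state.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector mu,
                              NumericVector sd, NumericMatrix ltrans,
                              NumericVector linit) {
  int T = x.size();
  IntegerVector path(T);
  if (T == 0) return path;
  NumericMatrix delta(T, 2);
  IntegerMatrix psi(T, 2);
  for (int s = 0; s < 2; s++) delta(0, s) = linit[s] + lgauss(x[0], mu[s], sd[s]);
  for (int t = 1; t < T; t++) {
    for (int s = 0; s < 2; s++) {
      double from0 = delta(t - 1, 0) + ltrans(0, s);
      double from1 = delta(t - 1, 1) + ltrans(1, s);
      // prefer linker (state 0) on ties
      if (from1 > from0) { delta(t, s) = from1; psi(t, s) = 1; }
      else { delta(t, s) = from0; psi(t, s) = 0; }
      delta(t, s) += lgauss(x[t], mu[s], sd[s]);
    }
  }
  int s = (delta(T - 1, 1) > delta(T - 1, 0)) ? 1 : 0;
  path[T - 1] = s;
  for (int t = T - 1; t > 0; t--) {
    s = psi(t, s);
    path[t - 1] = s;
  }
  return path;
}

// Scaled forward-backward for the 2-state Gaussian HMM; returns the
// log-likelihood and per-position posteriors (E-step of EM).
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericVector x, NumericVector mu,
                              NumericVector sd, NumericMatrix trans,
                              NumericVector init) {
  int T = x.size();
  NumericMatrix alpha(T, 2), beta(T, 2), gamma(T, 2);
  NumericVector scale(T);
  NumericMatrix b(T, 2);
  for (int t = 0; t < T; t++)
    for (int s = 0; s < 2; s++)
      b(t, s) = std::exp(lgauss(x[t], mu[s], sd[s]));

  for (int s = 0; s < 2; s++) alpha(0, s) = init[s] * b(0, s);
  scale[0] = alpha(0, 0) + alpha(0, 1);
  if (scale[0] <= 0) scale[0] = 1e-300;
  alpha(0, 0) /= scale[0]; alpha(0, 1) /= scale[0];
  for (int t = 1; t < T; t++) {
    for (int s = 0; s < 2; s++) {
      alpha(t, s) = (alpha(t - 1, 0) * trans(0, s) +
                     alpha(t - 1, 1) * trans(1, s)) * b(t, s);
    }
    scale[t] = alpha(t, 0) + alpha(t, 1);
    if (scale[t] <= 0) scale[t] = 1e-300;
    alpha(t, 0) /= scale[t]; alpha(t, 1) /= scale[t];
  }
  beta(T - 1, 0) = 1.0; beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; t--) {
    for (int s = 0; s < 2; s++) {
      beta(t, s) = (trans(s, 0) * b(t + 1, 0) * beta(t + 1, 0) +
                    trans(s, 1) * b(t + 1, 1) * beta(t + 1, 1)) / scale[t + 1];
    }
  }
  double ll = 0.0;
  for (int t = 0; t < T; t++) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double tot = g0 + g1;
    if (tot <= 0) tot = 1e-300;
    gamma(t, 0) = g0 / tot; gamma(t, 1) = g1 / tot;
    ll += std::log(scale[t]);
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma);
}
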