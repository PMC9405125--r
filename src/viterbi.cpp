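#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding of a linear-chain HMM with per-step symmetric transitions:
// one stay log-probability and one shared off-diagonal log-probability per
// step. Ties are broken by `pref`, a permutation of 0..S-1 in decreasing
// preference (most preferred first), applied both to the backpointers and to
// the terminal state, so decoding is fully deterministic.
//
// emis_ll: n x S matrix of emission log-likelihoods (natural log)
// log_prior: length-S initial state log-probabilities
// log_stay, log_off: length n-1 per-step transition log-probabilities
//
// Returns the MAP state path as 0-based state indices, with the path's joint
// log-likelihood in attribute "score".
// [[Rcpp::export]]
IntegerVector viterbi_path(NumericMatrix emis_ll, NumericVector log_prior,
                           NumericVector log_stay, NumericVector log_off,
                           IntegerVector pref) {
  const int n = emis_ll.nrow();
  const int S = emis_ll.ncol();
  if (n == 0) return IntegerVector(0);

  NumericMatrix delta(n, S);
  IntegerMatrix psi(n, S);
  for (int s = 0; s < S; ++s) delta(0, s) = log_prior[s] + emis_ll(0, s);

  for (int t = 1; t < n; ++t) {
    const double ls = log_stay[t - 1];
    const double lo = log_off[t - 1];
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf;
      int arg = pref[0];
      for (int k0 = 0; k0 < S; ++k0) {
        const int k = pref[k0];
        const double v = delta(t - 1, k) + (k == s ? ls : lo);
        if (v > best) {
          best = v;
          arg = k;
        }
      }
      delta(t, s) = best + emis_ll(t, s);
      psi(t, s) = arg;
    }
  }

  double best = R_NegInf;
  int last = pref[0];
  for (int k0 = 0; k0 < S; ++k0) {
    const int k = pref[k0];
    if (delta(n - 1, k) > best) {
      best = delta(n - 1, k);
      last = k;
    }
  }

  IntegerVector path(n);
  path[n - 1] = last;
  for (int t = n - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  path.attr("score") = best;
  return path;
}
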