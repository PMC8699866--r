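// Duration-constrained Viterbi decoding for the cyclic four-state
// heart-sound HSMM. States are 1..K in fixed cyclic order (state k is
// entered from state k-1, state 1 from state K). Initial and final runs
// may be censored (the recording starts/ends mid-run); censored runs are
// scored with the duration survival function.
#include <Rcpp.h>
using namespace Rcpp;

// logem:  T x K per-frame emission log probabilities
// logdur: K x Dmax duration log pmf
// logsf:  K x Dmax log P(duration >= d)
// Returns the maximum a-posteriori state path (length T, values 1..K).
// [[Rcpp::export]]
IntegerVector cpp_hsmm_viterbi(NumericMatrix logem, NumericMatrix logdur,
                               NumericMatrix logsf) {
  const int T = logem.nrow(), K = logem.ncol(), Dmax = logdur.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double logPrior = -std::log((double)K);

  // cumulative emission sums: ce(t,k) = sum_{u<=t} logem(u,k), ce(0,k)=0
  std::vector<double> ce((size_t)(T + 1) * K, 0.0);
  for (int k = 0; k < K; ++k)
    for (int t = 1; t <= T; ++t)
      ce[(size_t)t * K + k] = ce[(size_t)(t - 1) * K + k] + logem(t - 1, k);

  // delta(t,k): best score of a path whose run of state k ends exactly at t
  std::vector<double> delta((size_t)(T + 1) * K, NEG);
  std::vector<int> bestd((size_t)(T + 1) * K, 0);

  for (int t = 1; t <= T; ++t) {
    for (int k = 0; k < K; ++k) {
      int prev = (k + K - 1) % K;
      double best = NEG;
      int bd = 0;
      int dmax = std::min(Dmax, t);
      for (int d = 1; d <= dmax; ++d) {
        int t0 = t - d;
        double em = ce[(size_t)t * K + k] - ce[(size_t)t0 * K + k];
        double sc;
        if (t0 == 0) {  // left-censored initial run
          sc = logPrior + logsf(k, d - 1) + em;
        } else {
          double prior = delta[(size_t)t0 * K + prev];
          if (prior == NEG) continue;
          sc = prior + logdur(k, d - 1) + em;
        }
        if (sc > best) { best = sc; bd = d; }
      }
      delta[(size_t)t * K + k] = best;
      bestd[(size_t)t * K + k] = bd;
    }
  }

  // termination: final run of state k ending at T, right-censored
  double best = NEG;
  int bk = 0, bd = 0;
  for (int k = 0; k < K; ++k) {
    int prev = (k + K - 1) % K;
    int dmax = std::min(Dmax, T);
    for (int d = 1; d <= dmax; ++d) {
      int t0 = T - d;
      double em = ce[(size_t)T * K + k] - ce[(size_t)t0 * K + k];
      double sc;
      if (t0 == 0) {
        sc = logPrior + logsf(k, d - 1) + em;
      } else {
        double prior = delta[(size_t)t0 * K + prev];
        if (prior == NEG) continue;
        sc = prior + logsf(k, d - 1) + em;
      }
      if (sc > best) { best = sc; bk = k; bd = d; }
    }
  }
  if (best == NEG) stop("no feasible state path (T too short for Dmax?)");

  IntegerVector path(T);
  int t = T, k = bk, d = bd;
  while (t > 0) {
    for (int u = t - d; u < t; ++u) path[u] = k + 1;
    t -= d;
    if (t == 0) break;
    k = (k + K - 1) % K;
    d = bestd[(size_t)t * K + k];
    if (d <= 0) stop("backtrack failure");
  }
  return path;
}
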