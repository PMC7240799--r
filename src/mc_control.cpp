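#include <Rcpp.h>
using namespace Rcpp;

// Tabular Monte Carlo control with exploring starts on an empirical model.
//
// The model arrives flattened: supported (state, action) pairs are indexed
// 0..P-1, sorted by state then action code (lexicographic), so scanning a
// state's pairs in order and keeping strict improvements implements the
// smallest-code tie-break. Each pair owns a slice [off, off+len) of the
// transition arrays: next-state index, cumulative conditional probability
// and expected reward. Uses R's RNG so runs are reproducible via set.seed().
//
// [[Rcpp::export]]
List mc_control_cpp(IntegerVector pair_s, IntegerVector pair_a,
                    IntegerVector pair_off, IntegerVector pair_len,
                    IntegerVector t_next, NumericVector t_cum,
                    NumericVector t_rew,
                    IntegerVector sp_first, IntegerVector sp_n,
                    int n_states, int n_episodes, int horizon,
                    bool first_visit, bool random_init) {
  const int P = pair_s.size();
  RNGScope scope;

  NumericVector q(P);
  IntegerVector nret(P);
  if (random_init)
    for (int p = 0; p < P; ++p) q[p] = unif_rand() * 2.0 - 1.0;

  // policy: pair index per state (-1 where unsupported); random init
  std::vector<int> pol(n_states, -1);
  for (int s = 0; s < n_states; ++s)
    if (sp_n[s] > 0)
      pol[s] = sp_first[s] + (int)(unif_rand() * sp_n[s]) % sp_n[s];

  std::vector<int> ep_pair(horizon);
  std::vector<double> ep_rew(horizon);
  std::vector<double> suffix(horizon + 1);
  std::vector<int> seen_in(P, -1);      // episode id of a pair's first visit
  std::vector<int> pol_done(n_states, -1);

  for (int e = 0; e < n_episodes; ++e) {
    // exploring start: uniform over supported pairs
    int p = (int)(unif_rand() * P) % P;
    int len = 0;
    while (len < horizon) {
      ep_pair[len] = p;
      // sample next state from the pair's cumulative distribution
      double u = unif_rand();
      int off = pair_off[p], m = pair_len[p], j = 0;
      while (j < m - 1 && u > t_cum[off + j]) ++j;
      ep_rew[len] = t_rew[off + j];
      ++len;
      int ns = t_next[off + j];
      if (sp_n[ns] == 0) break;   // state with no observed actions
      p = pol[ns];
    }
    // returns: undiscounted suffix sums of the rewards
    suffix[len] = 0.0;
    for (int t = len - 1; t >= 0; --t) suffix[t] = suffix[t + 1] + ep_rew[t];
    for (int t = 0; t < len; ++t) {
      int pp = ep_pair[t];
      if (first_visit) {
        if (seen_in[pp] == e) continue;
        seen_in[pp] = e;
      }
      nret[pp] += 1;
      q[pp] += (suffix[t] - q[pp]) / nret[pp];
    }
    // greedy policy improvement at the states visited this episode
    for (int t = 0; t < len; ++t) {
      int s = pair_s[ep_pair[t]];
      if (pol_done[s] == e) continue;
      pol_done[s] = e;
      int best = sp_first[s];
      double bq = q[best];
      for (int k = 1; k < sp_n[s]; ++k) {
        int cand = sp_first[s] + k;
        if (q[cand] > bq) { bq = q[cand]; best = cand; }
      }
      pol[s] = best;
    }
  }

  return List::create(_["q"] = q, _["n"] = nret);
}
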