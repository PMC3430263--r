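#include <Rcpp.h>
using namespace Rcpp;

// Sample N candidate top-k lists from a k x n position/item probability
// matrix, filling positions sequentially without replacement. Uses R's RNG
// so set.seed() makes the draw reproducible. Returns 1-based item indices.
// [[Rcpp::export]]
IntegerMatrix cpp_ce_sample(NumericMatrix P, int N) {
  const int k = P.nrow(), n = P.ncol();
  IntegerMatrix out(N, k);
  std::vector<bool> used(n);
  for (int s = 0; s < N; ++s) {
    std::fill(used.begin(), used.end(), false);
    for (int pos = 0; pos < k; ++pos) {
      double total = 0.0;
      for (int j = 0; j < n; ++j)
        if (!used[j]) total += P(pos, j);
      int pick = -1;
      if (total > 0) {
        double u = unif_rand() * total, acc = 0.0;
        for (int j = 0; j < n; ++j) {
          if (used[j]) continue;
          acc += P(pos, j);
          if (u <= acc) { pick = j; break; }
        }
      }
      if (pick < 0) { // degenerate row: uniform over the unused items
        int left = 0;
        for (int j = 0; j < n; ++j) if (!used[j]) ++left;
        int r = (int)(unif_rand() * left);
        if (r >= left) r = left - 1;
        for (int j = 0; j < n; ++j)
          if (!used[j] && r-- == 0) { pick = j; break; }
      }
      used[pick] = true;
      out(s, pos) = pick + 1;
    }
  }
  return out;
}

// Batched weighted-footrule objective. `cand` holds 1-based item indices
// (one candidate list per row); `listRanks(i, t)` is the truncated rank of
// item t in input list i (k+1 when absent). Items absent from both lists
// contribute |(k+1)-(k+1)| = 0, so summing over the whole universe equals
// the union sum in the footrule definition.
// [[Rcpp::export]]
NumericVector cpp_phi_batch(IntegerMatrix cand, IntegerMatrix listRanks,
                            NumericVector W, int k) {
  const int N = cand.nrow(), kc = cand.ncol();
  const int m = listRanks.nrow(), n = listRanks.ncol();
  NumericVector phi(N);
  std::vector<int> r(n);
  for (int s = 0; s < N; ++s) {
    std::fill(r.begin(), r.end(), k + 1);
    for (int pos = 0; pos < kc; ++pos) r[cand(s, pos) - 1] = pos + 1;
    double tot = 0.0;
    for (int i = 0; i < m; ++i) {
      long d = 0;
      for (int t = 0; t < n; ++t) d += std::labs((long)r[t] - (long)listRanks(i, t));
      tot += W[i] * (double)d;
    }
    phi[s] = tot;
  }
  return phi;
}
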