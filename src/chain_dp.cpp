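#include <Rcpp.h>
using namespace Rcpp;

// Highest-scoring-path DP over anchors of one chromosome pair.
// Anchors must be sorted by (rank_a, rank_b). A transition j -> i requires
// strictly increasing rank_a, strictly monotone rank_b (direction given by
// `descending`), and midpoint distances <= D on both genomes. Transition
// penalty: g * (skipped genes on A + skipped genes on B). Per-anchor match
// score is capped at Z by the caller.
// [[Rcpp::export(name = ".chain_dp")]]
List chain_dp(IntegerVector ra, IntegerVector rb,
              NumericVector ma, NumericVector mb,
              NumericVector s, double D, double g, bool descending) {
  int n = ra.size();
  NumericVector dp(n);
  IntegerVector prev(n);
  for (int i = 0; i < n; ++i) {
    dp[i] = s[i];
    prev[i] = -1;
    for (int j = 0; j < i; ++j) {
      if (ra[j] >= ra[i]) continue;
      if (descending ? (rb[j] <= rb[i]) : (rb[j] >= rb[i])) continue;
      if (std::abs(ma[i] - ma[j]) > D) continue;
      if (std::abs(mb[i] - mb[j]) > D) continue;
      double pen = g * ((ra[i] - ra[j] - 1) + (std::abs(rb[i] - rb[j]) - 1));
      double cand = dp[j] + s[i] - pen;
      if (cand > dp[i]) {
        dp[i] = cand;
        prev[i] = j;
      }
    }
  }
  return List::create(_["score"] = dp, _["prev"] = prev);
}

// Empirical clustering test: per replicate, sample k of n SG indices
// uniformly without replacement (R RNG, so set.seed() reproduces results)
// and count, for each window, replicates whose in-window sampled count
// strictly exceeds the observed count.
// When `inclusive` is true, replicates tying the observed count are also
// counted (P(X >= obs)), which makes the empirical P value properly
// conservative; the default strict rule counts only exceedances.
// [[Rcpp::export(name = ".perm_window_test")]]
IntegerVector perm_window_test(int n, int k, IntegerVector win_start,
                               IntegerVector win_end, IntegerVector observed,
                               int n_reps, bool inclusive) {
  int nw = win_start.size();
  IntegerVector exceed(nw);
  std::vector<int> pool(n), cum(n + 1);
  for (int rep = 0; rep < n_reps; ++rep) {
    for (int i = 0; i < n; ++i) pool[i] = 0;
    // partial Fisher-Yates over 0..n-1 marking k sampled positions
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
      pool[idx[i]] = 1;
    }
    cum[0] = 0;
    for (int i = 0; i < n; ++i) cum[i + 1] = cum[i] + pool[i];
    for (int w = 0; w < nw; ++w) {
      int cnt = cum[win_end[w]] - cum[win_start[w] - 1];
      if (cnt > observed[w] || (inclusive && cnt == observed[w])) exceed[w]++;
    }
  }
  return exceed;
}
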