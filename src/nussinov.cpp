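#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

static inline bool can_pair(char a, char b, bool gu) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return true;
  if ((a == 'C' && b == 'G') || (a == 'G' && b == 'C')) return true;
  if (gu && ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'))) return true;
  return false;
}

// Maximum base-pair-count fold (Nussinov DP) with hairpin loops >= min_loop.
// Returns a 1-based partner table: partner[i] == j (and partner[j] == i) when
// bases i and j pair, 0 when unpaired. Traceback is deterministic: at each
// subproblem the 5' base pairs with the smallest admissible partner that
// achieves the optimum, else it is left unpaired.
// [[Rcpp::export]]
IntegerVector nussinov_pairs_cpp(std::string seq, int min_loop, bool allow_gu) {
  const int n = (int) seq.size();
  IntegerVector partner(n, 0);
  if (n < min_loop + 2) return partner;

  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = dp[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair(seq[i], seq[k], allow_gu)) {
          int v = 1;
          if (i + 1 <= k - 1) v += dp[i + 1][k - 1];
          if (k + 1 <= j) v += dp[k + 1][j];
          if (v > best) best = v;
        }
      }
      dp[i][j] = best;
    }
  }

  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first;
    const int j = stack.back().second;
    stack.pop_back();
    if (i >= j || dp[i][j] == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j && !paired; ++k) {
      if (can_pair(seq[i], seq[k], allow_gu)) {
        int v = 1;
        if (i + 1 <= k - 1) v += dp[i + 1][k - 1];
        if (k + 1 <= j) v += dp[k + 1][j];
        if (v == dp[i][j]) {
          partner[i] = k + 1;
          partner[k] = i + 1;
          if (i + 1 <= k - 1) stack.push_back(std::make_pair(i + 1, k - 1));
          if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
          paired = true;
        }
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return partner;
}
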