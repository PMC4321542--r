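#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Base-pair maximization (Nussinov-style) secondary structure for a DNA/RNA
// window. Watson-Crick pairs plus the G:U wobble (G:T in DNA alphabet),
// minimum hairpin loop of `min_loop` unpaired bases. Among structures with
// the maximal pair count the DP minimizes the summed distance of paired
// positions from the window center, which makes the traceback deterministic
// and biases ties toward stems near the middle of the window.

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T' || b == 'U';
  case 'C': return b == 'G';
  case 'G': return b == 'C' || b == 'T' || b == 'U';
  case 'T': case 'U': return b == 'A' || b == 'G';
  default: return false;
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  IntegerVector pairing(n, 0);
  if (n == 0)
    return List::create(_["pairing"] = pairing, _["max_pairs"] = 0);

  // cost of pairing position p (1-based): |2p - (n+1)| keeps integer math
  std::vector<int64_t> pcost(n);
  for (int p = 0; p < n; ++p) pcost[p] = std::llabs(2LL * (p + 1) - (n + 1));

  // DP tables over [i, j] 0-based inclusive
  std::vector<int> P((size_t) n * n, 0);        // max pairs
  std::vector<int64_t> C((size_t) n * n, 0);    // min center cost at max pairs
  auto idx = [n](int i, int j) { return (size_t) i * n + j; };

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // option 1: i unpaired
      int bp = (i + 1 <= j) ? P[idx(i + 1, j)] : 0;
      int64_t bc = (i + 1 <= j) ? C[idx(i + 1, j)] : 0;
      // option 2: i paired with k
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner_p = (i + 1 <= k - 1) ? P[idx(i + 1, k - 1)] : 0;
        int64_t inner_c = (i + 1 <= k - 1) ? C[idx(i + 1, k - 1)] : 0;
        int right_p = (k + 1 <= j) ? P[idx(k + 1, j)] : 0;
        int64_t right_c = (k + 1 <= j) ? C[idx(k + 1, j)] : 0;
        int p2 = inner_p + right_p + 1;
        int64_t c2 = inner_c + right_c + pcost[i] + pcost[k];
        if (p2 > bp || (p2 == bp && c2 < bc)) { bp = p2; bc = c2; }
      }
      P[idx(i, j)] = bp;
      C[idx(i, j)] = bc;
    }
  }

  // traceback replays the same comparison order
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    int bp = P[idx(i, j)];
    int64_t bc = C[idx(i, j)];
    if (bp == ((i + 1 <= j) ? P[idx(i + 1, j)] : 0) &&
        bc == ((i + 1 <= j) ? C[idx(i + 1, j)] : 0)) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    bool done = false;
    for (int k = i + min_loop + 1; k <= j && !done; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int inner_p = (i + 1 <= k - 1) ? P[idx(i + 1, k - 1)] : 0;
      int64_t inner_c = (i + 1 <= k - 1) ? C[idx(i + 1, k - 1)] : 0;
      int right_p = (k + 1 <= j) ? P[idx(k + 1, j)] : 0;
      int64_t right_c = (k + 1 <= j) ? C[idx(k + 1, j)] : 0;
      if (inner_p + right_p + 1 == bp &&
          inner_c + right_c + pcost[i] + pcost[k] == bc) {
        pairing[i] = k + 1;
        pairing[k] = i + 1;
        if (i + 1 <= k - 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) stack.push_back(std::make_pair(i + 1, j)); // defensive; unreachable
  }

  return List::create(_["pairing"] = pairing,
                      _["max_pairs"] = P[idx(0, n - 1)]);
}
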