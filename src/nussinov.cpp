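#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Watson-Crick + GU wobble pairing on DNA alphabet (T stands for U).
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default:  return false;
  }
}

// Maximum number of nested base pairs with a minimum hairpin loop of
// `min_loop` unpaired bases between any paired (i, j): j - i > min_loop.
// Classic O(n^3) dynamic program.
// [[Rcpp::export(name = ".nussinov_max_pairs")]]
int nussinov_max_pairs(std::string seq, int min_loop = 3) {
  int n = (int) seq.size();
  if (n == 0) return 0;
  for (auto &c : seq) {
    c = (char) toupper(c);
    if (c == 'U') c = 'T';
  }
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];                      // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) { // j paired with k
        if (!can_pair(seq[k], seq[j])) continue;
        int left = (k > i) ? M[i][k - 1] : 0;
        int inside = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
        int cand = left + inside + 1;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  return M[0][n - 1];
}
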