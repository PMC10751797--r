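#include <Rcpp.h>
#include <vector>
#include <utility>

using namespace Rcpp;

// Length of the longest (non-contiguous) common subsequence of two symbol
// vectors.  Classical O(|a|*|b|) dynamic programme with a rolling row, so
// memory stays O(min(|a|,|b|)) even for long uncondensed pathways.
// [[Rcpp::export]]
int lcs_length_cpp(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  if (m > n) { IntegerVector tmp = a; a = b; b = tmp; std::swap(n, m); }
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = prev[j] >= cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Longest common *substring* (contiguous) between a[lo1,hi1) and b[lo2,hi2).
static void longest_block(const IntegerVector &a, const IntegerVector &b,
                          int lo1, int hi1, int lo2, int hi2,
                          int &best_i, int &best_j, int &best_len) {
  best_len = 0; best_i = lo1; best_j = lo2;
  int m = hi2 - lo2;
  if (hi1 <= lo1 || m <= 0) return;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = lo1; i < hi1; ++i) {
    for (int j = lo2; j < hi2; ++j) {
      int jj = j - lo2 + 1;
      if (a[i] == b[j]) {
        cur[jj] = prev[jj - 1] + 1;
        if (cur[jj] > best_len) {
          best_len = cur[jj];
          best_i = i - cur[jj] + 1;
          best_j = j - cur[jj] + 1;
        }
      } else cur[jj] = 0;
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
}

// Total number of matched symbols under Ratcliff-Obershelp recursive
// matching blocks (the classical Gestalt pattern-matching count).
// [[Rcpp::export]]
int matching_blocks_cpp(IntegerVector a, IntegerVector b) {
  int total = 0;
  std::vector<std::pair<std::pair<int,int>, std::pair<int,int> > > stack;
  stack.push_back(std::make_pair(std::make_pair(0, (int)a.size()),
                                 std::make_pair(0, (int)b.size())));
  while (!stack.empty()) {
    int lo1 = stack.back().first.first,  hi1 = stack.back().first.second;
    int lo2 = stack.back().second.first, hi2 = stack.back().second.second;
    stack.pop_back();
    int bi, bj, blen;
    longest_block(a, b, lo1, hi1, lo2, hi2, bi, bj, blen);
    if (blen == 0) continue;
    total += blen;
    stack.push_back(std::make_pair(std::make_pair(lo1, bi),
                                   std::make_pair(lo2, bj)));
    stack.push_back(std::make_pair(std::make_pair(bi + blen, hi1),
                                   std::make_pair(bj + blen, hi2)));
  }
  return total;
}
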