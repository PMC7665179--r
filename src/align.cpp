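#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1, mismatch -1, gap -1.
// Optimum is taken lexicographically over (score, matches, -columns), so
// among equal-score alignments the one with most matches, then fewest
// columns, is chosen. Additive lexicographic tuples satisfy optimal
// substructure, so the DP is exact.

struct Cell {
  int score;
  int matches;
  int cols;
  char move; // 'D' diagonal, 'U' up (gap in b), 'L' left (gap in a)
};

static inline bool better(int s1, int m1, int c1, int s2, int m2, int c2) {
  if (s1 != s2) return s1 > s2;
  if (m1 != m2) return m1 > m2;
  return c1 < c2;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<Cell> dp((n + 1) * (m + 1));
  auto at = [&](int i, int j) -> Cell& { return dp[i * (m + 1) + j]; };

  at(0, 0) = {0, 0, 0, 0};
  for (int i = 1; i <= n; ++i) at(i, 0) = {-i, 0, i, 'U'};
  for (int j = 1; j <= m; ++j) at(0, j) = {-j, 0, j, 'L'};

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const bool match = (a[i - 1] == b[j - 1]);
      const Cell &d = at(i - 1, j - 1), &u = at(i - 1, j), &l = at(i, j - 1);
      int s = d.score + (match ? 1 : -1);
      int mm = d.matches + (match ? 1 : 0);
      int c = d.cols + 1;
      char mv = 'D';
      if (better(u.score - 1, u.matches, u.cols + 1, s, mm, c)) {
        s = u.score - 1; mm = u.matches; c = u.cols + 1; mv = 'U';
      }
      if (better(l.score - 1, l.matches, l.cols + 1, s, mm, c)) {
        s = l.score - 1; mm = l.matches; c = l.cols + 1; mv = 'L';
      }
      at(i, j) = {s, mm, c, mv};
    }
  }

  std::string aa, bb;
  aa.reserve(n + m); bb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    char mv = at(i, j).move;
    if (mv == 'D') { aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j; }
    else if (mv == 'U') { aa.push_back(a[i - 1]); bb.push_back('-'); --i; }
    else { aa.push_back('-'); bb.push_back(b[j - 1]); --j; }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  const Cell &fin = at(n, m);
  return List::create(
    _["a_aln"] = aa, _["b_aln"] = bb,
    _["matches"] = fin.matches, _["columns"] = fin.cols,
    _["score"] = fin.score);
}
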