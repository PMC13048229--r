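#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment over IUPAC bitmasks, linear gap
// penalty. Column score: identical masks -> match; overlapping masks ->
// compatible; disjoint -> mismatch. Traceback tie order is fixed
// (diagonal, then up = gap in b, then left = gap in a) so outputs are
// reproducible.
//
// Returns list(score, ops) where ops is an integer vector over alignment
// columns, left to right: 0 = diagonal, 1 = up (a consumed, gap in b),
// 2 = left (b consumed, gap in a).

// [[Rcpp::export(name = ".nw_align_masks")]]
List nw_align_masks(IntegerVector am, IntegerVector bm,
                    int match, int compatible, int mismatch, int gap) {
  const int n = am.size(), m = bm.size();
  // score matrix, row-major (n+1) x (m+1)
  std::vector<int> S((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) S[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    int *cur = &S[(size_t)i * (m + 1)];
    int *prev = &S[(size_t)(i - 1) * (m + 1)];
    cur[0] = i * gap;
    const int ai = am[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int bj = bm[j - 1];
      const int sub = (ai == bj) ? match : ((ai & bj) ? compatible : mismatch);
      int best = prev[j - 1] + sub;     // diagonal
      const int up = prev[j] + gap;     // gap in b
      if (up > best) best = up;
      const int left = cur[j - 1] + gap; // gap in a
      if (left > best) best = left;
      cur[j] = best;
    }
  }
  // traceback
  std::vector<int> rops;
  rops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int s = S[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0) {
      const int ai = am[i - 1], bj = bm[j - 1];
      const int sub = (ai == bj) ? match : ((ai & bj) ? compatible : mismatch);
      if (s == S[(size_t)(i - 1) * (m + 1) + (j - 1)] + sub) {
        rops.push_back(0); --i; --j; continue;
      }
    }
    if (i > 0 && s == S[(size_t)(i - 1) * (m + 1) + j] + gap) {
      rops.push_back(1); --i; continue;
    }
    rops.push_back(2); --j;
  }
  std::reverse(rops.begin(), rops.end());
  return List::create(_["score"] = S[(size_t)n * (m + 1) + m],
                      _["ops"] = IntegerVector(rops.begin(), rops.end()));
}
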