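#include <Rcpp.h>
#include <algorithm>
#include <cstdlib>
#include <string>
#include <vector>

using namespace Rcpp;

// Column score for a base pair.  'N' never matches (ambiguity code carries no
// identity information), so N-N and N-X are both mismatches.
static inline int subst_score(char x, char y, int match, int mismatch) {
  if (x == y && x != 'N') return match;
  return mismatch;
}

// Needleman-Wunsch global alignment with linear (per-column) gap penalty and a
// deterministic traceback: at every cell prefer the diagonal move
// (match/mismatch), then a gap in `a` (column consuming a base of b), then a
// gap in `b`.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("global alignment requires non-empty sequences");
  std::vector<int> M((size_t)(n + 1) * (m + 1));
  const int w = m + 1;
  for (int j = 0; j <= m; ++j) M[j] = gap * j;
  for (int i = 1; i <= n; ++i) {
    M[(size_t)i * w] = gap * i;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = M[(size_t)(i - 1) * w + (j - 1)] + subst_score(ai, b[j - 1], match, mismatch);
      int l = M[(size_t)i * w + (j - 1)] + gap;
      int u = M[(size_t)(i - 1) * w + j] + gap;
      int best = d;
      if (l > best) best = l;
      if (u > best) best = u;
      M[(size_t)i * w + j] = best;
    }
  }
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int cur = M[(size_t)i * w + j];
    if (i > 0 && j > 0 &&
        cur == M[(size_t)(i - 1) * w + (j - 1)] +
                   subst_score(a[i - 1], b[j - 1], match, mismatch)) {
      ra += a[i - 1]; rb += b[j - 1]; --i; --j;
    } else if (j > 0 && cur == M[(size_t)i * w + (j - 1)] + gap) {
      ra += '-'; rb += b[j - 1]; --j;
    } else {
      ra += a[i - 1]; rb += '-'; --i;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int matches = 0, mismatches = 0, gaps = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] == '-' || rb[k] == '-') ++gaps;
    else if (ra[k] == rb[k] && ra[k] != 'N') ++matches;
    else ++mismatches;
  }
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gap_columns"] = gaps, _["score"] = M[(size_t)n * w + m]);
}

// Banded Levenshtein distance with cutoff k: returns the unit-cost edit
// distance if it is <= k, otherwise k + 1.  Any alignment's
// mismatch+gap-column count is bounded below by this distance, so it is a
// safe pre-screen for the TSD acceptance rule (which caps that count at <= 3).
// 'N' is a substitution against everything, including itself.
// [[Rcpp::export(name = ".bounded_edit_cpp")]]
int bounded_edit_cpp(std::string a, std::string b, int k) {
  const int n = (int)a.size(), m = (int)b.size();
  if (k < 0) stop("k must be >= 0");
  if (std::abs(n - m) > k) return k + 1;
  const int INF = k + 1;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  for (int j = 0; j <= std::min(m, k); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    const int lo = std::max(1, i - k), hi = std::min(m, i + k);
    std::fill(cur.begin(), cur.end(), INF);
    int rowmin = INF;
    if (i - k <= 0) { cur[0] = i; rowmin = std::min(rowmin, cur[0]); }
    const char ai = a[i - 1];
    for (int j = lo; j <= hi; ++j) {
      const int costsub = (ai != b[j - 1] || ai == 'N') ? 1 : 0;
      int best = INF;
      if (prev[j - 1] + costsub < best) best = prev[j - 1] + costsub;
      if (prev[j] + 1 < best) best = prev[j] + 1;
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      cur[j] = best > INF ? INF : best;
      if (cur[j] < rowmin) rowmin = cur[j];
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  return prev[m] > k ? k + 1 : prev[m];
}
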