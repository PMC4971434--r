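// Banded global / semi-global alignment with unit costs (match 0,
// mismatch 1, gap 1). "a" is the reference-side string; free_a_prefix /
// free_a_suffix allow unpenalized skipping of reference sequence at the
// window edges (used when aligning contig tails into an oversized
// reference window).
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int band,
                      bool free_a_prefix = false,
                      bool free_a_suffix = false) {
  const int n = (int)a.size(), m = (int)b.size();
  const int INF = std::numeric_limits<int>::max() / 4;
  // allowed diagonal offsets d = j - i; a strict band around the main
  // diagonal, so an alignment whose length difference exceeds the band is
  // reported unaligned (callers widen the band to cover expected drift)
  const int lo = -band;
  const int hi = band;
  const int W = hi - lo + 1;
  if (W <= 0) stop("empty band");
  std::vector<int> dp((size_t)(n + 1) * W, INF);
  auto at = [&](int i, int j) -> int& {
    return dp[(size_t)i * W + (j - i - lo)];
  };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j - i >= lo && j - i <= hi;
  };
  at(0, 0) = 0;
  for (int j = 1; j <= m && inband(0, j); ++j) at(0, j) = j;
  for (int i = 1; i <= n; ++i) {
    if (inband(i, 0)) at(i, 0) = free_a_prefix ? 0 : i;
    int jmin = std::max(1, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int best = INF;
      int d = at(i - 1, j - 1);  // always in band
      if (d < INF) best = d + (a[i - 1] == b[j - 1] ? 0 : 1);
      if (inband(i - 1, j)) {
        int u = at(i - 1, j);
        if (u < INF && u + 1 < best) best = u + 1;
      }
      if (inband(i, j - 1)) {
        int l = at(i, j - 1);
        if (l < INF && l + 1 < best) best = l + 1;
      }
      at(i, j) = best;
    }
  }
  // terminal cell: optionally free trailing reference
  int end_i = n, cost;
  if (free_a_suffix) {
    int besti = -1, bestc = INF;
    for (int i = 0; i <= n; ++i) {
      if (!inband(i, m)) continue;
      int c = at(i, m);
      if (c < bestc) { bestc = c; besti = i; }
    }
    if (besti < 0) return List::create(_["aligned"] = false);
    end_i = besti; cost = bestc;
  } else {
    if (!inband(n, m) || at(n, m) >= INF)
      return List::create(_["aligned"] = false);
    cost = at(n, m);
  }
  if (cost >= INF) return List::create(_["aligned"] = false);
  // traceback; gap moves are preferred on ties so that backward tracing
  // yields contiguous, leftmost-placed gap runs (splitting an InDel run
  // around a matching base would otherwise be an equal-cost alternative)
  std::string ra, rb;
  int i = end_i, j = m;
  while (i > 0 || j > 0) {
    if (free_a_prefix && j == 0) break;
    int cur = at(i, j);
    if (i > 0 && inband(i - 1, j) && at(i - 1, j) < INF &&
        cur == at(i - 1, j) + 1) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else if (j > 0 && inband(i, j - 1) && at(i, j - 1) < INF &&
               cur == at(i, j - 1) + 1) {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    } else if (i > 0 && j > 0 && at(i - 1, j - 1) < INF &&
               cur == at(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else {
      stop("traceback failure (internal error)");
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned"] = true, _["cost"] = cost,
                      _["a_aln"] = ra, _["b_aln"] = rb,
                      _["a_start"] = i + 1, _["a_end"] = end_i);
}
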