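// Variable-length LCSk chaining of anchors (stage III).
//
// Selects a subset of anchors, strictly increasing in both read and region
// start coordinates, maximizing the total credited covered length.  Each
// substring has the length of its anchor (the variable-length relaxation of
// fixed-k LCSk).  A later anchor partially overlapping its predecessor is
// kept but its credit is reduced by the larger of its read- and region-side
// overlaps; credit never goes negative.  Because the credit is a pairwise
// function of (predecessor, successor), the chain is computed with an exact
// O(n^2) dynamic programme (anchor counts per region are small); an
// exhaustive-subset oracle backs this in the tests.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_lcsk_chain(IntegerVector qstart, IntegerVector qend,
                    IntegerVector tstart, IntegerVector tend) {
  int n = qstart.size();
  if (n == 0)
    return List::create(_["index"] = IntegerVector(0),
                        _["credit"] = IntegerVector(0),
                        _["total"] = 0);
  // deterministic processing order
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (qstart[a] != qstart[b]) return qstart[a] < qstart[b];
    if (tstart[a] != tstart[b]) return tstart[a] < tstart[b];
    if (qend[a] != qend[b]) return qend[a] < qend[b];
    return tend[a] < tend[b];
  });

  std::vector<long> dp(n);
  std::vector<int> prev(n, -1), credit(n);
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    int len = qend[i] - qstart[i];
    long best = len;           // start a new chain
    int bprev = -1, bcred = len;
    for (int oj = 0; oj < oi; ++oj) {
      int j = ord[oj];
      if (qstart[j] >= qstart[i] || tstart[j] >= tstart[i]) continue;
      int pen = std::max(0, std::max(qend[j] - qstart[i], tend[j] - tstart[i]));
      int cred = std::max(0, len - pen);
      long sc = dp[j] + cred;
      if (sc > best ||
          (sc == best && bprev >= 0 &&
           (tend[j] < tend[bprev] ||
            (tend[j] == tend[bprev] && j < bprev)))) {
        best = sc; bprev = j; bcred = cred;
      }
    }
    dp[i] = best; prev[i] = bprev; credit[i] = bcred;
  }

  // best chain end: max score, ties by smaller tend then smaller index
  int end = ord[0];
  for (int oi = 1; oi < n; ++oi) {
    int i = ord[oi];
    if (dp[i] > dp[end] ||
        (dp[i] == dp[end] &&
         (tend[i] < tend[end] || (tend[i] == tend[end] && i < end))))
      end = i;
  }
  std::vector<int> sel, cred;
  for (int cur = end; cur >= 0; cur = prev[cur]) {
    sel.push_back(cur + 1);  // 1-based for R
    cred.push_back(credit[cur]);
  }
  std::reverse(sel.begin(), sel.end());
  std::reverse(cred.begin(), cred.end());
  return List::create(_["index"] = wrap(sel), _["credit"] = wrap(cred),
                      _["total"] = (double)dp[end]);
}
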