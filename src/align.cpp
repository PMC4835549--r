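// Final-alignment kernels (stage V).
//
// Semi-global ("infix") alignment consumes the whole read with free gaps at
// the region ends.  Location and edit distance come from Myers' bit-vector
// algorithm (block formulation with carry propagation); the CIGAR is then
// reconstructed by a banded dynamic programme over the localized window,
// with band slack derived from the bit-vector distance so the optimum is
// provably inside the band.  A Gotoh affine-gap semi-global aligner is
// provided as an alternative mode.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <limits>
#include "nm_util.h"

using namespace Rcpp;

namespace {

const uint64_t HIGH_BIT = 1ULL << 63;

// One 64-row block of a Myers bit-vector column step.  `out_mask` selects
// the row whose horizontal delta is reported (bit 63 for interior blocks,
// the last real query row for the final block; rows above it in the final
// block are virtual and never influence lower rows because carries only
// propagate upward).
inline int calc_block(uint64_t& Pv, uint64_t& Mv, uint64_t Eq, int hin,
                      uint64_t out_mask) {
  uint64_t hin_neg = (uint64_t)(hin >> 1) & 1ULL;  // 1 iff hin == -1
  uint64_t Xv = Eq | Mv;
  Eq |= hin_neg;
  uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
  uint64_t Ph = Mv | ~(Xh | Pv);
  uint64_t Mh = Pv & Xh;
  int hout = 0;
  if (Ph & out_mask) hout = 1;
  else if (Mh & out_mask) hout = -1;
  Ph <<= 1; Mh <<= 1;
  Mh |= hin_neg;
  if (hin > 0) Ph |= 1ULL;
  Pv = Mh | ~(Xv | Ph);
  Mv = Ph & Xv;
  return hout;
}

// Myers bit-vector scan, infix task: free text gaps at both ends, whole
// query consumed.  Tracks the score at the last query row across all text
// columns.  Returns the best (distance, text end); ties prefer the smaller
// end position.
void myers_infix(const std::string& query, const std::string& text,
                 int& best_dist, int& best_end) {
  int m = (int)query.size(), n = (int)text.size();
  int W = (m + 63) / 64;
  uint64_t last_mask = 1ULL << ((m - 1) % 64);
  std::vector<uint64_t> Peq(5 * W, 0);
  for (int i = 0; i < m; ++i) {
    int c = nm_code(query[i]);
    if (c >= 0) Peq[(size_t)c * W + i / 64] |= 1ULL << (i % 64);
  }
  std::vector<uint64_t> Pv(W, ~0ULL), Mv(W, 0);
  int score = m;
  best_dist = m; best_end = 0;  // empty prefix: m insertions
  for (int j = 0; j < n; ++j) {
    int c = nm_code(text[j]);
    if (c < 0) c = 4;
    int hin = 0;
    for (int b = 0; b < W; ++b)
      hin = calc_block(Pv[b], Mv[b], Peq[(size_t)c * W + b], hin,
                       b == W - 1 ? last_mask : HIGH_BIT);
    score += hin;
    if (score < best_dist) { best_dist = score; best_end = j + 1; }
  }
}

const int NM_INF = std::numeric_limits<int>::max() / 4;

// Banded global edit-distance DP with traceback.  `slack` must be >= the
// optimal distance for the result to be exact.  Returns distance and writes
// the extended CIGAR ops (=, X, I, D; query-consuming ops I and =/X).
int banded_global(const std::string& q, const std::string& t, int slack,
                  std::string& ops) {
  int m = (int)q.size(), w = (int)t.size();
  int lo = std::min(0, w - m) - slack, hi = std::max(0, w - m) + slack;
  lo = std::max(lo, -m); hi = std::min(hi, w);
  int B = hi - lo + 1;
  std::vector<int> prevrow_v(B + 2, NM_INF), currow_v(B + 2, NM_INF);
  // +1 sentinel on each side so b-1 / b+1 never need bounds checks
  int* prow = prevrow_v.data() + 1;
  int* crow = currow_v.data() + 1;
  std::vector<uint8_t> tb((size_t)(m + 1) * B);
  const char* qs = q.data();
  const char* ts = t.data();
  // row 0: D[0][j] = j for j in band
  for (int j = std::max(0, lo); j <= std::min(w, hi); ++j) {
    prow[j - lo] = j;
    tb[j - lo] = 3;  // left (D)
  }
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(0, i + lo), jhi = std::min(w, i + hi);
    int blo = jlo - i - lo, bhi = jhi - i - lo;
    uint8_t* tbrow = tb.data() + (size_t)i * B;
    if (blo > 0) crow[blo - 1] = NM_INF;
    if (bhi < B - 1) crow[bhi + 1] = NM_INF;
    char qc = qs[i - 1];
    bool qvalid = nm_code(qc) >= 0;
    int b = blo, j = jlo;
    if (j == 0) {  // first column: only vertical moves
      int u = prow[b + 1];
      crow[b] = u < NM_INF ? u + 1 : NM_INF;
      tbrow[b] = 2;
      ++b; ++j;
    }
    for (; b <= bhi; ++b, ++j) {
      bool match = qvalid && qc == ts[j - 1];
      int best = prow[b] + (match ? 0 : 1);  // diag (i-1, j-1), same offset
      uint8_t dir = match ? 0 : 1;
      int u = prow[b + 1] + 1;  // up (i-1, j) -> I
      if (u < best) { best = u; dir = 2; }
      int lft = crow[b - 1] + 1;  // left (i, j-1) -> D
      if (lft < best) { best = lft; dir = 3; }
      crow[b] = best;
      tbrow[b] = dir;
    }
    std::swap(prow, crow);
  }
  int endb = w - m - lo;
  if (endb < 0 || endb >= B || prow[endb] >= NM_INF) return NM_INF;
  int dist = prow[endb];
  ops.clear();
  int i = m, j = w;
  while (i > 0 || j > 0) {
    uint8_t dir = tb[(size_t)i * B + (j - i - lo)];
    switch (dir) {
      case 0: ops.push_back('='); --i; --j; break;
      case 1: ops.push_back('X'); --i; --j; break;
      case 2: ops.push_back('I'); --i; break;
      default: ops.push_back('D'); --j; break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return dist;
}

std::string compress_ops(const std::string& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out.push_back(ops[i]);
    i = j;
  }
  return out;
}

}  // namespace

// Edit distance + best end position of the infix alignment (bit-vector path
// only; exposed so tests can check it against a plain DP oracle).
// [[Rcpp::export]]
List cpp_myers_infix(std::string query, std::string text) {
  int d, e;
  myers_infix(query, text, d, e);
  return List::create(_["dist"] = d, _["end"] = e);
}

// Full semi-global alignment: bit-vector scans locate the window, banded DP
// reconstructs the path.  Returns 0-based [start, end) on the text.
// [[Rcpp::export]]
List cpp_align_semiglobal(std::string query, std::string text) {
  if (query.empty() || text.empty())
    stop("semi-global alignment requires non-empty sequences");
  int d, end;
  myers_infix(query, text, d, end);
  int start = 0;
  if (end > 0) {
    std::string rq(query.rbegin(), query.rend());
    std::string rt(text.rbegin() + (text.size() - end), text.rend());
    int rd, rend;
    myers_infix(rq, rt, rd, rend);
    start = end - rend;
  }
  std::string ops;
  std::string sub = text.substr(start, end - start);
  int dist = banded_global(query, sub, d + 1, ops);
  return List::create(_["edit"] = dist, _["start"] = start, _["end"] = end,
                      _["cigar"] = compress_ops(ops));
}

// Global edit alignment of two (sub)sequences with band doubling; used for
// intra/inter-cluster pieces of the anchored mode.
// [[Rcpp::export]]
List cpp_align_global(std::string query, std::string text) {
  int m = (int)query.size(), w = (int)text.size();
  if (m == 0 && w == 0)
    return List::create(_["edit"] = 0, _["cigar"] = "");
  std::string ops;
  int slack = std::max(8, std::abs(w - m) / 8 + 1);
  int dist = NM_INF;
  while (true) {
    dist = banded_global(query, text, slack, ops);
    if (dist <= slack || slack >= m + w) break;
    slack = std::min(slack * 2, m + w);
  }
  return List::create(_["edit"] = dist, _["cigar"] = compress_ops(ops));
}

// Stitch a filtered anchor set into a full alignment: exact co-linear
// anchor bodies are emitted by direct comparison, inter-anchor gaps (which
// include structural-variant gaps between clusters) are aligned with the
// banded global kernel, and read-end extensions are soft-clipped.  Anchors
// must be monotone; overlaps are trimmed equally on both coordinates, which
// preserves co-linearity.
// [[Rcpp::export]]
List cpp_anchored_stitch(std::string read, std::string region,
                         IntegerVector qstart, IntegerVector qend,
                         IntegerVector tstart, IntegerVector tend) {
  int n = qstart.size();
  if (n == 0) stop("anchored stitching requires at least one anchor");
  std::string ops;
  long edit = 0;
  int rl = (int)read.size();
  int prev_qe = -1, prev_te = -1, first_ts = -1;
  int lead_clip = 0, tail_clip = 0;
  for (int i = 0; i < n; ++i) {
    int qs = qstart[i], qe = qend[i], ts = tstart[i], te = tend[i];
    if (prev_qe < 0) {
      lead_clip = qs;
      first_ts = ts;
    } else {
      int trim = std::max(0, std::max(prev_qe - qs, prev_te - ts));
      qs += trim; ts += trim;
      if (qs >= qe || ts >= te) continue;
      if (qs > prev_qe || ts > prev_te) {
        std::string gq = read.substr(prev_qe, qs - prev_qe);
        std::string gt = region.substr(prev_te, ts - prev_te);
        int m = (int)gq.size(), w = (int)gt.size();
        std::string gops;
        if (m == 0 && w == 0) {
        } else if (m == 0) {
          gops.assign((size_t)w, 'D');
        } else if (w == 0) {
          gops.assign((size_t)m, 'I');
        } else {
          int slack = std::max(16, std::abs(w - m) / 4 + 16);
          int dist;
          while (true) {
            dist = banded_global(gq, gt, slack, gops);
            if (dist <= slack || slack >= m + w) break;
            slack = std::min(slack * 2, m + w);
          }
          edit += dist;
        }
        if (m == 0 || w == 0) edit += std::max(m, w);
        ops += gops;
      }
    }
    for (int p = 0; p < qe - qs; ++p) {
      bool match = read[qs + p] == region[ts + p] && nm_code(read[qs + p]) >= 0;
      ops.push_back(match ? '=' : 'X');
      if (!match) ++edit;
    }
    prev_qe = qe; prev_te = te;
  }
  tail_clip = rl - prev_qe;
  std::string cig;
  if (lead_clip > 0) cig = std::to_string(lead_clip) + "S";
  cig += compress_ops(ops);
  if (tail_clip > 0) cig += std::to_string(tail_clip) + "S";
  return List::create(_["cigar"] = cig, _["edit"] = (double)edit,
                      _["tstart"] = first_ts, _["tend"] = prev_te);
}

// [[Rcpp::export]]
std::string cpp_merge_cigar(std::string cigar) {
  // re-compress after concatenation: parse and merge adjacent equal ops
  std::string out;
  long len = 0, cur = 0;
  char op = 0;
  for (char c : cigar) {
    if (c >= '0' && c <= '9') { cur = cur * 10 + (c - '0'); }
    else {
      if (c == op) len += cur;
      else {
        if (op) { out += std::to_string(len); out.push_back(op); }
        op = c; len = cur;
      }
      cur = 0;
    }
  }
  if (op) { out += std::to_string(len); out.push_back(op); }
  return out;
}

// Gotoh semi-global affine-gap alignment (maximizing).  Free text gaps at
// both ends; whole query consumed.  Gap of length g costs open + g * extend.
// [[Rcpp::export]]
List cpp_gotoh_semiglobal(std::string query, std::string text,
                          int match, int mismatch, int gap_open, int gap_extend) {
  int m = (int)query.size(), n = (int)text.size();
  if (m == 0 || n == 0)
    stop("semi-global alignment requires non-empty sequences");
  if ((double)(m + 1) * (n + 1) > 4e8)
    stop("sequences too long for the full-matrix Gotoh aligner");
  const int NEG = std::numeric_limits<int>::min() / 4;
  size_t cols = (size_t)n + 1;
  std::vector<int> Mp(cols), Xp(cols), Yp(cols), Mc(cols), Xc(cols), Yc(cols);
  std::vector<uint8_t> tb((size_t)(m + 1) * cols, 0);
  // tb bits: 0-1 pred of M (0=M,1=X,2=Y), 2-3 pred of X, 4-5 pred of Y
  for (size_t j = 0; j <= (size_t)n; ++j) { Mp[j] = 0; Xp[j] = NEG; Yp[j] = NEG; }
  for (int i = 1; i <= m; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = gap_open + gap_extend * i;
    tb[(size_t)i * cols] |= (i == 1 ? 0 : 1) << 2;
    for (int j = 1; j <= n; ++j) {
      // M: diagonal
      int dm = Mp[j - 1], dx = Xp[j - 1], dy = Yp[j - 1];
      int best = dm; uint8_t pm = 0;
      if (dx > best) { best = dx; pm = 1; }
      if (dy > best) { best = dy; pm = 2; }
      int s = (query[i - 1] == text[j - 1] && nm_code(query[i - 1]) >= 0)
                  ? match : mismatch;
      Mc[j] = best > NEG ? best + s : NEG;
      // X: gap in text (query base consumed; SAM 'I')
      int xo_m = Mp[j] > NEG ? Mp[j] + gap_open + gap_extend : NEG;
      int xo_y = Yp[j] > NEG ? Yp[j] + gap_open + gap_extend : NEG;
      int xe = Xp[j] > NEG ? Xp[j] + gap_extend : NEG;
      int bx = xo_m; uint8_t px = 0;
      if (xe > bx) { bx = xe; px = 1; }
      if (xo_y > bx) { bx = xo_y; px = 2; }
      Xc[j] = bx;
      // Y: gap in query (text base consumed; SAM 'D')
      int yo_m = Mc[j - 1] > NEG ? Mc[j - 1] + gap_open + gap_extend : NEG;
      int yo_x = Xc[j - 1] > NEG ? Xc[j - 1] + gap_open + gap_extend : NEG;
      int ye = Yc[j - 1] > NEG ? Yc[j - 1] + gap_extend : NEG;
      int by = yo_m; uint8_t py = 0;
      if (ye > by) { by = ye; py = 1; }
      if (yo_x > by) { by = yo_x; py = 2; }
      Yc[j] = by;
      tb[(size_t)i * cols + j] = pm | (px << 2) | (py << 4);
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  // free trailing text gap: best over last row
  int bestj = 0, bests = NEG, bstate = 0;
  for (int j = 0; j <= n; ++j) {
    int v[3] = {Mp[j], Xp[j], Yp[j]};
    for (int s = 0; s < 3; ++s)
      if (v[s] > bests) { bests = v[s]; bestj = j; bstate = s; }
  }
  std::string ops;
  int i = m, j = bestj, state = bstate;
  while (i > 0) {
    uint8_t b = tb[(size_t)i * cols + j];
    if (state == 0) {
      ops.push_back(query[i - 1] == text[j - 1] && nm_code(query[i - 1]) >= 0
                        ? '=' : 'X');
      state = b & 3; --i; --j;
    } else if (state == 1) {
      ops.push_back('I');
      int px = (b >> 2) & 3;
      state = (px == 0) ? 0 : (px == 1 ? 1 : 2);
      --i;
    } else {
      ops.push_back('D');
      int py = (b >> 4) & 3;
      state = (py == 0) ? 0 : (py == 1 ? 2 : 1);
      --j;
    }
  }
  int start = j;
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = bests, _["start"] = start, _["end"] = bestj,
                      _["cigar"] = compress_ops(ops));
}
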