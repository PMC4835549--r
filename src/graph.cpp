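// Vertex-centric walk over the kmer mapping graph of the read (stage II).
//
// Vertices are the read's kmers (identical kmers stay separate vertices, one
// per position).  Each vertex has l outbound edges to the next l read kmers,
// letting a walk jump over kmers corrupted by sequencing errors.  Region
// kmers are processed left to right; each hit (read position i, region
// position j) either extends the best existing walk ending at a read
// position in {i-l, ..., i-1} (best = longest covered walk; ties prefer the
// smallest read gap, then the earliest origin) subject to the reference-gap
// constraint 1 <= j - j' <= l, or starts a new walk.  The per-hit update is
// O(l * cell capacity), i.e. constant for fixed l.
//
// Walks may shift diagonal (bridging indels); they are split into maximal
// co-linear segments which become the exact-match anchors downstream.

#include <Rcpp.h>
#include <vector>
#include <array>
#include "nm_util.h"

using namespace Rcpp;

namespace {

struct State {
  int last_i, last_j;       // read / region position of the last kmer
  int q_origin, t_origin;   // first kmer of the walk
  int walk_len;             // bases covered on the read (kmer advances clipped at k)
  int cov_kmers;
  int parent;               // previous state in the walk, -1 for a root
  bool extended;            // superseded by a successor state
};

const int CELL_CAP = 4;     // live states kept per read position

}  // namespace

// [[Rcpp::export]]
List cpp_graph_walk(std::string query, std::string target, int k, int l) {
  // `query` is the read (graph vertices), `target` the region sequence whose
  // kmers drive the traversal.
  int nq = (int)query.size(), nt = (int)target.size();
  List empty = List::create(
      _["walks"] = DataFrame::create(
          _["walk"] = IntegerVector(0), _["qstart"] = IntegerVector(0),
          _["qend"] = IntegerVector(0), _["tstart"] = IntegerVector(0),
          _["tend"] = IntegerVector(0), _["walk_length"] = IntegerVector(0),
          _["covered_kmers"] = IntegerVector(0)),
      _["anchors"] = DataFrame::create(
          _["walk"] = IntegerVector(0), _["qstart"] = IntegerVector(0),
          _["qend"] = IntegerVector(0), _["tstart"] = IntegerVector(0),
          _["tend"] = IntegerVector(0), _["covered_bases"] = IntegerVector(0),
          _["covered_kmers"] = IntegerVector(0)));
  if (k < 1 || k >= 16 || nq < k || nt < k) return empty;

  // Perfect kmer hashing of the read (k < 10 by default): kmer code -> all
  // read positions, kept separate.
  size_t tbl_size = (size_t)1 << (2 * k);
  std::vector<std::vector<int>> tbl(tbl_size);
  {
    uint32_t code = 0, mask = (uint32_t)(tbl_size - 1);
    int run = 0;
    for (int i = 0; i < nq; ++i) {
      int c = nm_code(query[i]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      if (++run >= k) tbl[code].push_back(i - k + 1);
    }
  }

  std::vector<State> states;
  states.reserve(1024);
  // cells[i]: indices of recent states whose last kmer is at read position i
  std::vector<std::array<int, CELL_CAP>> cells(nq);
  std::vector<int> ncell(nq, 0);

  uint32_t code = 0, mask = (uint32_t)(tbl_size - 1);
  int run = 0;
  for (int j = 0; j < nt; ++j) {
    int c = nm_code(target[j]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run < k) continue;
    int jk = j - k + 1;  // region kmer position
    const std::vector<int>& hits = tbl[code];
    for (int i : hits) {
      // best predecessor among read positions i-1 .. i-l
      int best = -1, best_len = -1, best_di = 0;
      for (int di = 1; di <= l && i - di >= 0; ++di) {
        int ip = i - di;
        for (int s = 0; s < ncell[ip]; ++s) {
          int sid = cells[ip][s];
          const State& st = states[sid];
          int dj = jk - st.last_j;
          if (dj < 1 || dj > l) continue;
          if (st.walk_len > best_len ||
              (st.walk_len == best_len && best >= 0 &&
               (di < best_di ||
                (di == best_di && st.q_origin < states[best].q_origin)))) {
            best = sid; best_len = st.walk_len; best_di = di;
          }
        }
      }
      State ns;
      ns.last_i = i; ns.last_j = jk;
      if (best >= 0) {
        State& ps = states[best];
        ns.q_origin = ps.q_origin; ns.t_origin = ps.t_origin;
        ns.walk_len = ps.walk_len + std::min(k, i - ps.last_i);
        ns.cov_kmers = ps.cov_kmers + 1;
        ns.parent = best;
        ps.extended = true;
      } else {
        ns.q_origin = i; ns.t_origin = jk;
        ns.walk_len = k; ns.cov_kmers = 1; ns.parent = -1;
      }
      ns.extended = false;
      int sid = (int)states.size();
      states.push_back(ns);
      // insert at read position i (ring-push, newest first)
      int& nc = ncell[i];
      if (nc < CELL_CAP) nc++;
      for (int s = nc - 1; s > 0; --s) cells[i][s] = cells[i][s - 1];
      cells[i][0] = sid;
    }
  }

  // Terminal states (never extended) are the walks; trace parents to split
  // into co-linear segments.
  std::vector<int> w_id, w_qs, w_qe, w_ts, w_te, w_len, w_kmers;
  std::vector<int> a_id, a_qs, a_qe, a_ts, a_te, a_cb, a_ck;
  std::vector<int> path;
  int walk_id = 0;
  for (size_t sid = 0; sid < states.size(); ++sid) {
    if (states[sid].extended) continue;
    const State& st = states[sid];
    path.clear();
    for (int cur = (int)sid; cur >= 0; cur = states[cur].parent) path.push_back(cur);
    std::reverse(path.begin(), path.end());
    w_id.push_back(walk_id);
    w_qs.push_back(st.q_origin); w_qe.push_back(st.last_i + k);
    w_ts.push_back(st.t_origin); w_te.push_back(st.last_j + k);
    w_len.push_back(st.walk_len); w_kmers.push_back(st.cov_kmers);
    // co-linear segments: consecutive kmers with equal read/region advance
    int seg_qs = states[path[0]].last_i, seg_ts = states[path[0]].last_j;
    int prev_i = seg_qs, prev_j = seg_ts, seg_cb = k, seg_ck = 1;
    for (size_t p = 1; p <= path.size(); ++p) {
      bool flush = (p == path.size());
      int ci = 0, cj = 0;
      if (!flush) {
        ci = states[path[p]].last_i; cj = states[path[p]].last_j;
        if (ci - prev_i != cj - prev_j) flush = true;  // diagonal shift
      }
      if (flush) {
        a_id.push_back(walk_id);
        a_qs.push_back(seg_qs); a_qe.push_back(prev_i + k);
        a_ts.push_back(seg_ts); a_te.push_back(prev_j + k);
        a_cb.push_back(seg_cb); a_ck.push_back(seg_ck);
        if (p < path.size()) {
          seg_qs = ci; seg_ts = cj; seg_cb = k; seg_ck = 1;
          prev_i = ci; prev_j = cj;
        }
      } else {
        seg_cb += std::min(k, ci - prev_i);
        seg_ck += 1;
        prev_i = ci; prev_j = cj;
      }
    }
    ++walk_id;
  }

  return List::create(
      _["walks"] = DataFrame::create(
          _["walk"] = wrap(w_id), _["qstart"] = wrap(w_qs), _["qend"] = wrap(w_qe),
          _["tstart"] = wrap(w_ts), _["tend"] = wrap(w_te),
          _["walk_length"] = wrap(w_len), _["covered_kmers"] = wrap(w_kmers)),
      _["anchors"] = DataFrame::create(
          _["walk"] = wrap(a_id), _["qstart"] = wrap(a_qs), _["qend"] = wrap(a_qe),
          _["tstart"] = wrap(a_ts), _["tend"] = wrap(a_te),
          _["covered_bases"] = wrap(a_cb), _["covered_kmers"] = wrap(a_ck)));
}
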