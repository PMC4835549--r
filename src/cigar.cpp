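// CIGAR walking and pileup helpers shared by the evaluation module.

#include <Rcpp.h>
#include <vector>
#include "nm_util.h"

using namespace Rcpp;

namespace {

// parse "12=3I..." into (len, op) pairs
std::vector<std::pair<int, char>> parse_cigar(const std::string& cig) {
  std::vector<std::pair<int, char>> out;
  int len = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') { len = len * 10 + (c - '0'); }
    else { out.push_back({len, c}); len = 0; }
  }
  return out;
}

inline bool consumes_query(char op) {
  return op == 'M' || op == '=' || op == 'X' || op == 'I' || op == 'S';
}
inline bool consumes_ref(char op) {
  return op == 'M' || op == '=' || op == 'X' || op == 'D';
}

}  // namespace

// For each query base (0-based), the 0-based reference coordinate it is
// placed at, or NA for insertions and soft clips.
// [[Rcpp::export]]
IntegerVector cpp_cigar_qmap(std::string cigar, int pos) {
  auto runs = parse_cigar(cigar);
  int qlen = 0;
  for (auto& r : runs) if (consumes_query(r.second)) qlen += r.first;
  IntegerVector map(qlen, NA_INTEGER);
  int q = 0, t = pos;
  for (auto& r : runs) {
    char op = r.second;
    for (int i = 0; i < r.first; ++i) {
      if (consumes_query(op) && consumes_ref(op)) { map[q++] = t++; }
      else if (consumes_query(op)) { ++q; }
      else if (consumes_ref(op)) { ++t; }
    }
  }
  return map;
}

// Run-level view: op, length, 0-based ref start (for I: the junction
// coordinate), 0-based query start.
// [[Rcpp::export]]
DataFrame cpp_cigar_runs(std::string cigar, int pos) {
  auto runs = parse_cigar(cigar);
  int n = (int)runs.size();
  CharacterVector op(n); IntegerVector len(n), tpos(n), qpos(n);
  int q = 0, t = pos;
  for (int i = 0; i < n; ++i) {
    op[i] = std::string(1, runs[i].second);
    len[i] = runs[i].first;
    tpos[i] = t; qpos[i] = q;
    if (consumes_query(runs[i].second)) q += runs[i].first;
    if (consumes_ref(runs[i].second)) t += runs[i].first;
  }
  return DataFrame::create(_["op"] = op, _["len"] = len, _["tpos"] = tpos,
                           _["qpos"] = qpos, _["stringsAsFactors"] = false);
}

// Base/deletion pileup over one reference.  Returns a (reflen x 5) count
// matrix (A, C, G, T, deletion), a coverage vector (aligned reads covering
// each position, M/=/X or D), and the raw insertion events (0-based junction
// position, inserted sequence).
// [[Rcpp::export]]
List cpp_pileup(IntegerVector pos, CharacterVector cigars, CharacterVector seqs,
                int reflen) {
  IntegerMatrix counts(reflen, 5);
  IntegerVector cov(reflen);
  std::vector<int> ins_pos;
  std::vector<std::string> ins_seq;
  for (int a = 0; a < pos.size(); ++a) {
    auto runs = parse_cigar(as<std::string>(cigars[a]));
    std::string seq = as<std::string>(seqs[a]);
    int q = 0, t = pos[a];
    for (auto& r : runs) {
      char op = r.second;
      if (op == 'M' || op == '=' || op == 'X') {
        for (int i = 0; i < r.first; ++i, ++q, ++t) {
          if (t < 0 || t >= reflen) continue;
          int c = nm_code(seq[q]);
          if (c >= 0) counts(t, c)++;
          cov[t]++;
        }
      } else if (op == 'D') {
        for (int i = 0; i < r.first; ++i, ++t) {
          if (t < 0 || t >= reflen) continue;
          counts(t, 4)++;
          cov[t]++;
        }
      } else if (op == 'I') {
        if (t >= 0 && t <= reflen) {
          ins_pos.push_back(t);
          ins_seq.push_back(seq.substr(q, r.first));
        }
        q += r.first;
      } else if (op == 'S') {
        q += r.first;
      }
    }
  }
  return List::create(_["counts"] = counts, _["cov"] = cov,
                      _["ins_pos"] = wrap(ins_pos), _["ins_seq"] = wrap(ins_seq));
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return nm_revcomp(s); }
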