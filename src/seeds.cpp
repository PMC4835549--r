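// Gapped spaced-seed indexing and indel-tolerant lookup (stage I seeding).
//
// A shape is a string over {1,0}: '1' positions contribute to the key, '0'
// ("don't care", DC) positions absorb a mismatch, a 1 bp deletion or a 1 bp
// insertion through three alternative lookup layouts per DC position.  The
// index stores one key per reference position (inclusive bases only); lookup
// enumerates the Cartesian product of the three layouts over all DC
// positions (3^d variants, deduplicated).

#include <Rcpp.h>
#include <algorithm>
#include <unordered_set>
#include "nm_util.h"

using namespace Rcpp;

struct ShapeLayouts {
  std::string pattern;
  int weight;
  int dc_count;
  std::vector<int> index_offsets;            // offsets of '1' positions
  std::vector<std::vector<int>> lookup_offsets; // 3^d variants (incl. index layout)
};

// Enumerate per-DC layout combinations.  Choice 0 = mismatch (skip the DC
// base), 1 = deletion (subsequent offsets shift by -1), 2 = insertion
// (subsequent offsets shift by +1).
static ShapeLayouts shape_layouts(const std::string& pat) {
  ShapeLayouts sl;
  sl.pattern = pat;
  sl.weight = 0;
  sl.dc_count = 0;
  std::vector<int> dc_pos;
  for (size_t i = 0; i < pat.size(); ++i) {
    if (pat[i] == '1') { sl.index_offsets.push_back((int)i); sl.weight++; }
    else { dc_pos.push_back((int)i); sl.dc_count++; }
  }
  int d = sl.dc_count;
  int ncomb = 1;
  for (int i = 0; i < d; ++i) ncomb *= 3;
  for (int comb = 0; comb < ncomb; ++comb) {
    std::vector<int> choice(d);
    int c = comb;
    for (int i = 0; i < d; ++i) { choice[i] = c % 3; c /= 3; }
    std::vector<int> offs;
    int shift = 0, dci = 0;
    for (size_t i = 0; i < pat.size(); ++i) {
      if (pat[i] == '1') {
        offs.push_back((int)i + shift);
      } else {
        if (choice[dci] == 1) shift -= 1;
        else if (choice[dci] == 2) shift += 1;
        ++dci;
      }
    }
    sl.lookup_offsets.push_back(offs);
  }
  return sl;
}

static bool key_at(const std::string& seq, int pos, const std::vector<int>& offs,
                   uint32_t& key) {
  key = 0;
  int n = (int)seq.size();
  for (int o : offs) {
    int p = pos + o;
    if (p < 0 || p >= n) return false;
    int c = nm_code(seq[p]);
    if (c < 0) return false;
    key = (key << 2) | (uint32_t)c;
  }
  return true;
}

struct ShapeIndex {
  ShapeLayouts layouts;
  // postings sorted by key; payload packs (ref_id << 32 | pos)
  std::vector<uint32_t> keys;
  std::vector<uint64_t> payload;
  // direct key -> postings-range table for weight <= 12 (O(1) lookup);
  // heavier shapes fall back to binary search
  std::vector<uint32_t> offsets;
};

struct SeedIndexSet {
  std::vector<ShapeIndex> shapes;
  std::vector<int> ref_lens;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector refs, CharacterVector patterns) {
  SeedIndexSet* idx = new SeedIndexSet();
  for (int r = 0; r < refs.size(); ++r)
    idx->ref_lens.push_back((int)LENGTH(STRING_ELT(refs, r)));
  for (int s = 0; s < patterns.size(); ++s) {
    ShapeIndex si;
    si.layouts = shape_layouts(as<std::string>(patterns[s]));
    std::vector<std::pair<uint32_t, uint64_t>> entries;
    int span = (int)si.layouts.pattern.size();
    for (int r = 0; r < refs.size(); ++r) {
      std::string ref = as<std::string>(refs[r]);
      int n = (int)ref.size();
      for (int p = 0; p + span <= n; ++p) {
        uint32_t key;
        if (key_at(ref, p, si.layouts.index_offsets, key))
          entries.push_back({key, ((uint64_t)r << 32) | (uint32_t)p});
      }
    }
    std::sort(entries.begin(), entries.end());
    si.keys.reserve(entries.size());
    si.payload.reserve(entries.size());
    for (auto& e : entries) { si.keys.push_back(e.first); si.payload.push_back(e.second); }
    if (si.layouts.weight <= 12) {
      size_t nk = (size_t)1 << (2 * si.layouts.weight);
      si.offsets.assign(nk + 1, 0);
      for (uint32_t k : si.keys) si.offsets[k + 1]++;
      for (size_t k = 1; k <= nk; ++k) si.offsets[k] += si.offsets[k - 1];
    }
    idx->shapes.push_back(std::move(si));
  }
  XPtr<SeedIndexSet> ptr(idx, true);
  return ptr;
}

static std::string key_string(uint32_t key, int w) {
  static const char* b = "ACGT";
  std::string s(w, 'A');
  for (int i = w - 1; i >= 0; --i) { s[i] = b[key & 3]; key >>= 2; }
  return s;
}

// Dump all postings of one shape's index (small references; tests only).
// [[Rcpp::export]]
DataFrame cpp_index_entries(SEXP xp, int shape_id) {
  XPtr<SeedIndexSet> idx(xp);
  const ShapeIndex& si = idx->shapes.at(shape_id);
  int w = si.layouts.weight;
  CharacterVector key((int)si.keys.size());
  IntegerVector ref((int)si.keys.size()), pos((int)si.keys.size());
  for (size_t i = 0; i < si.keys.size(); ++i) {
    key[i] = key_string(si.keys[i], w);
    ref[i] = (int)(si.payload[i] >> 32);
    pos[i] = (int)(si.payload[i] & 0xffffffffu);
  }
  return DataFrame::create(_["key"] = key, _["ref"] = ref, _["pos"] = pos,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
IntegerVector cpp_index_ref_lens(SEXP xp) {
  XPtr<SeedIndexSet> idx(xp);
  return wrap(idx->ref_lens);
}

static void collect_strand(const SeedIndexSet& idx, const std::string& read,
                           int strand, int cap,
                           std::vector<int>& qpos, std::vector<int>& tpos,
                           std::vector<int>& rid, std::vector<int>& str,
                           std::vector<int>& shp) {
  int n = (int)read.size();
  for (size_t s = 0; s < idx.shapes.size(); ++s) {
    const ShapeIndex& si = idx.shapes[s];
    std::vector<uint32_t> seen;
    for (int p = 0; p < n; ++p) {
      seen.clear();
      for (const auto& offs : si.layouts.lookup_offsets) {
        uint32_t key;
        if (!key_at(read, p, offs, key)) continue;  // only layouts that fit
        if (std::find(seen.begin(), seen.end(), key) != seen.end()) continue;
        seen.push_back(key);
        size_t lo, hi;
        if (!si.offsets.empty()) {
          lo = si.offsets[key]; hi = si.offsets[key + 1];
        } else {
          lo = std::lower_bound(si.keys.begin(), si.keys.end(), key) -
               si.keys.begin();
          hi = std::upper_bound(si.keys.begin() + lo, si.keys.end(), key) -
               si.keys.begin();
        }
        if (hi == lo || (long)(hi - lo) > cap) continue;  // high-frequency cap
        for (size_t i = lo; i < hi; ++i) {
          qpos.push_back(p);
          tpos.push_back((int)(si.payload[i] & 0xffffffffu));
          rid.push_back((int)(si.payload[i] >> 32));
          str.push_back(strand);
          shp.push_back((int)s);
        }
      }
    }
  }
}

// Look up every read position (both strands) against every shape index.
// Returns 0-based positions; strand 0 = '+', 1 = '-' (qpos on the
// reverse-complemented read for '-' hits).
// [[Rcpp::export]]
List cpp_collect_hits(SEXP xp, std::string read, int cap) {
  XPtr<SeedIndexSet> idx(xp);
  std::vector<int> qpos, tpos, rid, str, shp;
  collect_strand(*idx, read, 0, cap, qpos, tpos, rid, str, shp);
  std::string rc = nm_revcomp(read);
  collect_strand(*idx, rc, 1, cap, qpos, tpos, rid, str, shp);
  return List::create(_["qpos"] = wrap(qpos), _["tpos"] = wrap(tpos),
                      _["ref"] = wrap(rid), _["strand"] = wrap(str),
                      _["shape"] = wrap(shp));
}

// Lookup-key enumeration for one position (used to cross-check the R-level
// implementation and in seed-recovery tests).
// [[Rcpp::export]]
CharacterVector cpp_lookup_keys(std::string seq, int pos, std::string pattern) {
  ShapeLayouts sl = shape_layouts(pattern);
  std::vector<std::string> out;
  for (const auto& offs : sl.lookup_offsets) {
    uint32_t key;
    if (!key_at(seq, pos, offs, key)) continue;
    std::string ks = key_string(key, sl.weight);
    if (std::find(out.begin(), out.end(), ks) == out.end()) out.push_back(ks);
  }
  return wrap(out);
}
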