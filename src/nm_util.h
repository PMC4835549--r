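#ifndef NM_UTIL_H
#define NM_UTIL_H

#include <string>
#include <vector>
#include <cstdint>

// 2-bit base codes; -1 for anything outside ACGT (case-insensitive).
inline int nm_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char nm_comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

inline std::string nm_revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = nm_comp(c);
  return r;
}

#endif
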