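// Plurality-vote consensus over recorded support alignments.  For every
// template position the supports vote with a base (match or mismatch
// column), a deletion, or an insertion string attached before the next
// template position; maximal runs of positions with support count >=
// min_cov are emitted with their plurality sequence.

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <string>
#include <vector>
#include <map>
#include <unordered_map>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_consensus(std::string tpl, IntegerVector t_start,
                   CharacterVector transcript, CharacterVector csub,
                   int min_cov = 4) {
  const int L = (int)tpl.size();
  const int S = t_start.size();
  std::vector<int> cov((size_t)L, 0);
  std::vector<std::array<int, 5>> cnt((size_t)L, {0, 0, 0, 0, 0}); // A C G T del
  std::unordered_map<int, std::map<std::string, int>> ins;
  auto code = [](char c) {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
                 case 'T': return 3; }
    return 0;
  };
  for (int s = 0; s < S; ++s) {
    std::string ops = as<std::string>(transcript[s]);
    std::string cs = as<std::string>(csub[s]);
    int ti = t_start[s];
    size_t ci = 0, i = 0;
    const size_t n = ops.size();
    while (i < n) {
      char op = ops[i];
      if (op == 'M' || op == 'X') {
        if (ti >= 0 && ti < L && ci < cs.size()) {
          cnt[(size_t)ti][(size_t)code(cs[ci])]++; cov[(size_t)ti]++;
        }
        ++ti; ++ci; ++i;
      } else if (op == 'D') {
        if (ti >= 0 && ti < L) { cnt[(size_t)ti][4]++; cov[(size_t)ti]++; }
        ++ti; ++i;
      } else {  // 'I' run
        std::string str;
        while (i < n && ops[i] == 'I') { if (ci < cs.size()) str.push_back(cs[ci]); ++ci; ++i; }
        if (ti > 0 && ti < L && !str.empty()) ins[ti][str]++;
      }
    }
  }
  const char* bases = "ACGT";
  std::vector<int> starts, ends;
  std::vector<std::string> seqs;
  int p = 0;
  while (p < L) {
    if (cov[(size_t)p] < min_cov) { ++p; continue; }
    int s = p;
    std::string out;
    while (p < L && cov[(size_t)p] >= min_cov) {
      if (p > s) {
        auto it = ins.find(p);
        if (it != ins.end()) {
          int bestc = 0; const std::string* bests = nullptr;
          for (auto& kv : it->second)
            if (kv.second > bestc) { bestc = kv.second; bests = &kv.first; }
          int ctx = std::min(cov[(size_t)(p - 1)], cov[(size_t)p]);
          if (bests && 2 * bestc > ctx) out += *bests;
        }
      }
      const auto& c = cnt[(size_t)p];
      int bi = 0;
      for (int b = 1; b < 4; ++b) if (c[(size_t)b] > c[(size_t)bi]) bi = b;
      if (c[4] <= c[(size_t)bi]) out.push_back(bases[bi]);  // deletion only on strict win
      ++p;
    }
    starts.push_back(s); ends.push_back(p); seqs.push_back(out);
  }
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                      _["seq"] = wrap(seqs), _["coverage"] = wrap(cov));
}
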