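// Canonical k-mer index over a read set, DDF seed scoring and co-linear
// chaining of k-mer pairs.  The index stores sampled (read, offset, strand)
// postings for each canonical k-mer; a template is scanned at stride 1 so
// that sampled candidate positions are always visible.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

static inline int base_code2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

struct Posting { int32_t rid; int32_t pos; uint8_t rc; };

struct KIndex {
  int k, stride, max_occ;
  std::vector<int> lens;
  std::unordered_map<uint64_t, std::vector<Posting>> tab;
};

static inline uint64_t revcomp_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (3 - (x & 3)); x >>= 2; }
  return r;
}

// Walk sequence s, calling f(pos, canonical_code, strand_bit) at every
// position with a full ACGT-only k-mer.  strand_bit 0 = canonical equals
// the forward k-mer, 1 = canonical equals its reverse complement.
template <typename F>
static void each_kmer(const std::string& s, int k, F f) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code2(s[(size_t)i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++valid < k) continue;
    uint64_t rc = revcomp_code(code, k);
    if (code <= rc) f(i - k + 1, code, 0);
    else            f(i - k + 1, rc, 1);
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k = 13, int stride = 5,
                     int max_occ = 500) {
  if (k < 2 || k > 21) stop("k must be in [2, 21]");
  if (stride < 1) stop("stride must be >= 1");
  KIndex* idx = new KIndex();
  idx->k = k; idx->stride = stride; idx->max_occ = max_occ;
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    idx->lens.push_back((int)s.size());
    each_kmer(s, k, [&](int pos, uint64_t code, int strand) {
      if (pos % stride != 0) return;
      idx->tab[code].push_back({r, pos, (uint8_t)strand});
    });
  }
  if (max_occ > 0)
    for (auto it = idx->tab.begin(); it != idx->tab.end();)
      it = ((int)it->second.size() > max_occ) ? idx->tab.erase(it) : ++it;
  XPtr<KIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<KIndex> idx(xp);
  size_t np = 0;
  for (auto& kv : idx->tab) np += kv.second.size();
  return List::create(_["k"] = idx->k, _["stride"] = idx->stride,
                      _["n_kmers"] = (double)idx->tab.size(),
                      _["n_postings"] = (double)np,
                      _["n_reads"] = (int)idx->lens.size());
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("k-mer length does not match index k");
  uint64_t code = 0;
  for (char c : kmer) {
    int b = base_code2(c);
    if (b < 0) stop("k-mer contains a non-ACGT base");
    code = (code << 2) | (uint64_t)b;
  }
  uint64_t rc = revcomp_code(code, idx->k);
  uint64_t canon = std::min(code, rc);
  std::vector<int> rid, pos; std::vector<std::string> strand;
  auto it = idx->tab.find(canon);
  if (it != idx->tab.end())
    for (const Posting& p : it->second) {
      rid.push_back(p.rid + 1); pos.push_back(p.pos);
      strand.push_back(p.rc ? "-" : "+");
    }
  return DataFrame::create(_["read"] = rid, _["pos"] = pos,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Longest strictly-increasing chain over pairs sorted by (tpos asc, cpos
// desc); returns indices of chain members.
static std::vector<int> lis_chain(const std::vector<std::pair<int, int>>& pr) {
  int n = (int)pr.size();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (pr[a].first != pr[b].first) return pr[a].first < pr[b].first;
    return pr[a].second > pr[b].second;
  });
  std::vector<int> tails;          // index into order of smallest tail cpos
  std::vector<int> pre(n, -1), at(n, -1);
  for (int oi = 0; oi < n; ++oi) {
    int i = order[(size_t)oi];
    int c = pr[(size_t)i].second;
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {                     // first tail with cpos >= c
      int mid = (lo + hi) / 2;
      if (pr[(size_t)tails[(size_t)mid]].second < c) lo = mid + 1; else hi = mid;
    }
    pre[(size_t)i] = (lo > 0) ? tails[(size_t)(lo - 1)] : -1;
    if (lo == (int)tails.size()) tails.push_back(i); else tails[(size_t)lo] = i;
    at[(size_t)i] = lo;
  }
  std::vector<int> chain;
  if (!tails.empty())
    for (int i = tails.back(); i != -1; i = pre[(size_t)i]) chain.push_back(i);
  std::reverse(chain.begin(), chain.end());
  return chain;
}

// Direct access to the chain kernel (test oracle comparisons).
// [[Rcpp::export]]
int cpp_lis_chain(IntegerVector tpos, IntegerVector cpos) {
  std::vector<std::pair<int, int>> pr;
  for (int i = 0; i < tpos.size(); ++i)
    pr.emplace_back(tpos[i], cpos[i]);
  return (int)lis_chain(pr).size();
}

struct Hit {
  int cand, strand, score;
  int t_start, t_end, c_start, c_end, seed_t, seed_c;
  std::vector<int> ch_t, ch_c;
};

static void scan_candidate(const std::vector<int>& tp, const std::vector<int>& cp,
                           int clen, int k, int strand, int epsilon,
                           int min_chain, int max_pairs, bool keep_chain,
                           int cand_id, std::vector<Hit>& out) {
  int n = (int)tp.size();
  if (n < min_chain) return;
  std::vector<std::pair<int, int>> pr;     // (tpos, cpos oriented)
  pr.reserve((size_t)n);
  for (int i = 0; i < n; ++i) {
    int c = strand ? (clen - k - cp[(size_t)i]) : cp[(size_t)i];
    pr.emplace_back(tp[(size_t)i], c);
  }
  if ((int)pr.size() > max_pairs) {
    std::vector<std::pair<int, int>> sub;
    double step = (double)pr.size() / max_pairs;
    for (int i = 0; i < max_pairs; ++i) sub.push_back(pr[(size_t)(i * step)]);
    pr.swap(sub);
    n = max_pairs;
  }
  // DDF score per pair: count of other pairs with |gamma_i - gamma_j| <= eps
  std::vector<int> gamma(n), order(n);
  for (int i = 0; i < n; ++i) { gamma[i] = pr[(size_t)i].first - pr[(size_t)i].second; order[i] = i; }
  std::sort(order.begin(), order.end(), [&](int a, int b) { return gamma[a] < gamma[b]; });
  std::vector<int> score(n);
  int lo = 0, hi = 0, best = -1;
  for (int oi = 0; oi < n; ++oi) {
    int i = order[(size_t)oi];
    while (gamma[order[(size_t)lo]] < gamma[(size_t)i] - epsilon) ++lo;
    while (hi < n && gamma[order[(size_t)hi]] <= gamma[(size_t)i] + epsilon) ++hi;
    score[(size_t)i] = hi - lo - 1;
    if (best < 0 || score[(size_t)i] > score[(size_t)best] ||
        (score[(size_t)i] == score[(size_t)best] &&
         (pr[(size_t)i].first < pr[(size_t)best].first ||
          (pr[(size_t)i].first == pr[(size_t)best].first &&
           pr[(size_t)i].second < pr[(size_t)best].second))))
      best = i;
  }
  int gseed = gamma[(size_t)best];
  std::vector<std::pair<int, int>> sup;
  for (int i = 0; i < n; ++i)
    if (std::abs(gamma[(size_t)i] - gseed) <= epsilon) sup.push_back(pr[(size_t)i]);
  std::vector<int> chain = lis_chain(sup);
  if ((int)chain.size() < min_chain) return;
  Hit h;
  h.cand = cand_id; h.strand = strand; h.score = (int)chain.size();
  h.t_start = sup[(size_t)chain.front()].first;
  h.t_end = sup[(size_t)chain.back()].first + k;
  h.c_start = sup[(size_t)chain.front()].second;
  h.c_end = sup[(size_t)chain.back()].second + k;
  const auto& mid = sup[(size_t)chain[(size_t)(chain.size() / 2)]];
  h.seed_t = mid.first; h.seed_c = mid.second;
  if (keep_chain)
    for (int ci : chain) {
      h.ch_t.push_back(sup[(size_t)ci].first);
      h.ch_c.push_back(sup[(size_t)ci].second);
    }
  out.push_back(std::move(h));
}

static List hits_to_list(const std::vector<Hit>& hits, bool keep_chain) {
  int n = (int)hits.size();
  IntegerVector cand(n), score(n), ts(n), te(n), cs(n), ce(n), st(n), sc(n);
  CharacterVector strand(n);
  List chains(keep_chain ? n : 0);
  for (int i = 0; i < n; ++i) {
    const Hit& h = hits[(size_t)i];
    cand[i] = h.cand + 1; strand[i] = h.strand ? "-" : "+"; score[i] = h.score;
    ts[i] = h.t_start; te[i] = h.t_end; cs[i] = h.c_start; ce[i] = h.c_end;
    st[i] = h.seed_t; sc[i] = h.seed_c;
    if (keep_chain)
      chains[i] = DataFrame::create(_["tpos"] = wrap(h.ch_t), _["cpos"] = wrap(h.ch_c));
  }
  DataFrame df = DataFrame::create(
    _["cand"] = cand, _["strand"] = strand, _["score"] = score,
    _["t_start"] = ts, _["t_end"] = te, _["c_start"] = cs, _["c_end"] = ce,
    _["seed_t"] = st, _["seed_c"] = sc, _["stringsAsFactors"] = false);
  return keep_chain ? List::create(_["hits"] = df, _["chains"] = chains)
                    : List::create(_["hits"] = df);
}

// [[Rcpp::export]]
List cpp_scan_template(SEXP xp, std::string tseq, int self0 = -1,
                       int epsilon = 32, int min_chain = 3,
                       int max_pairs = 2000, bool keep_chain = false) {
  XPtr<KIndex> idx(xp);
  const int k = idx->k;
  // gather pairs per (candidate, strand)
  std::unordered_map<uint64_t, std::pair<std::vector<int>, std::vector<int>>> acc;
  each_kmer(tseq, k, [&](int pos, uint64_t code, int tstrand) {
    auto it = idx->tab.find(code);
    if (it == idx->tab.end()) return;
    for (const Posting& p : it->second) {
      if (p.rid == self0) continue;
      int rel = (tstrand == (int)p.rc) ? 0 : 1;
      auto& v = acc[((uint64_t)p.rid << 1) | (uint64_t)rel];
      v.first.push_back(pos); v.second.push_back(p.pos);
    }
  });
  std::vector<Hit> hits;
  std::vector<uint64_t> keys;
  keys.reserve(acc.size());
  for (auto& kv : acc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  for (uint64_t key : keys) {
    auto& v = acc[key];
    int rid = (int)(key >> 1), strand = (int)(key & 1);
    scan_candidate(v.first, v.second, idx->lens[(size_t)rid], k, strand,
                   epsilon, min_chain, max_pairs, keep_chain, rid, hits);
  }
  return hits_to_list(hits, keep_chain);
}

// [[Rcpp::export]]
List cpp_scan_pair(std::string tseq, std::string cseq, int k = 13,
                   int stride = 5, int epsilon = 32, int min_chain = 3,
                   bool keep_chain = true) {
  CharacterVector v(1); v[0] = cseq;
  SEXP xp = cpp_build_index(v, k, stride, 0);
  return cpp_scan_template(xp, tseq, -1, epsilon, min_chain, 2000, keep_chain);
}
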