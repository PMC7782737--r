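// Alignment kernels.
//
// Distance-only paths use Myers' blocked bit-parallel algorithm (global in
// the text start, free or fixed text end).  Transcript paths use a banded
// scalar DP whose band is sized from a previously computed distance, so the
// banded result is exact.  Blockwise extension follows the template /
// candidate pair outward from a seed in 500 bp blocks, re-anchoring the
// band at every block boundary and stopping when a block pair exceeds the
// per-block error ceiling.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return 0;
}

// ---------------------------------------------------------------------------
// Myers bit-parallel core
// ---------------------------------------------------------------------------

// Bottom-row scores of the edit matrix of `pat` (rows, start fixed) against
// `txt` (columns, start fixed: D[0][j] = j).  If `semi` is true the minimum
// over all columns (free text end) is returned together with its column;
// otherwise the score after the last column (global) is returned.
static void myers_core(const char* pat, int m, const char* txt, int n,
                       bool semi, long* out_dist, int* out_end) {
  if (m == 0) { *out_dist = semi ? 0 : n; *out_end = semi ? 0 : n; return; }
  const int W = (m + 63) / 64;
  std::vector<uint64_t> peq(4 * (size_t)W, 0), VP((size_t)W, ~0ULL), VN((size_t)W, 0);
  for (int i = 0; i < m; ++i)
    peq[(size_t)base_code(pat[i]) * W + (i >> 6)] |= 1ULL << (i & 63);
  long score = m;
  long best = m; int bestj = 0;
  const int last = W - 1;
  const uint64_t last_mask = 1ULL << ((m - 1) & 63);
  for (int j = 0; j < n; ++j) {
    const uint64_t* eqc = &peq[(size_t)base_code(txt[j]) * W];
    int hin = 1;  // text start fixed: top boundary accrues +1 per column
    for (int w = 0; w < W; ++w) {
      uint64_t Eq = eqc[w];
      uint64_t X = Eq;
      if (hin < 0) X |= 1ULL;
      uint64_t VPw = VP[w], VNw = VN[w];
      uint64_t D0 = ((VPw + (X & VPw)) ^ VPw) | X | VNw;
      uint64_t HN = VPw & D0;
      uint64_t HP = VNw | ~(VPw | D0);
      uint64_t mask = (w == last) ? last_mask : (1ULL << 63);
      int hout = (HP & mask) ? 1 : ((HN & mask) ? -1 : 0);
      HP <<= 1; HN <<= 1;
      if (hin > 0) HP |= 1ULL;
      if (hin < 0) HN |= 1ULL;
      VP[w] = HN | ~(D0 | HP);
      VN[w] = HP & D0;
      hin = hout;
    }
    score += hin;
    if (semi && (score < best || (score == best))) { best = score; bestj = j + 1; }
  }
  if (semi) { *out_dist = best; *out_end = bestj; }
  else      { *out_dist = score; *out_end = n; }
}

// Exact global (Levenshtein) edit distance.
// [[Rcpp::export]]
long cpp_edit_distance(std::string a, std::string b) {
  long d; int e;
  myers_core(a.data(), (int)a.size(), b.data(), (int)b.size(), false, &d, &e);
  return d;
}

// Semi-global: whole of `pat` against a prefix of `txt` of free length.
// Returns c(distance, text_end).
// [[Rcpp::export]]
IntegerVector cpp_semiglobal_distance(std::string pat, std::string txt) {
  long d; int e;
  myers_core(pat.data(), (int)pat.size(), txt.data(), (int)txt.size(), true, &d, &e);
  return IntegerVector::create((int)d, e);
}

// ---------------------------------------------------------------------------
// Banded global alignment with traceback
// ---------------------------------------------------------------------------

// Exact when band >= final distance; callers either pass a known distance
// bound or rely on the doubling wrapper below.  Ops: M match, X mismatch,
// D = A-only column (A char unmatched), I = B-only column.
static bool banded_tb_try(const char* A, int n, const char* B, int m, int band,
                          long* out_dist, std::string* out_ops) {
  if (band < std::abs(n - m) + 1) band = std::abs(n - m) + 1;
  const int width = 2 * band + 1;
  const int BIG = 1 << 28;
  if ((size_t)(n + 1) * (size_t)width > (size_t)1.6e9) stop("alignment band too large");
  // rows padded with one sentinel on each side: offset o = j - i + band + 1
  std::vector<int> prev((size_t)width + 2, BIG), cur((size_t)width + 2, BIG);
  std::vector<uint8_t> moves((size_t)(n + 1) * width, 0);  // 1 diag, 2 up(A), 3 left(B)
  for (int j = 0; j <= std::min(m, band); ++j) prev[(size_t)(j + band + 1)] = j;
  for (int i = 1; i <= n; ++i) {
    const int lo = std::max(0, i - band), hi = std::min(m, i + band);
    uint8_t* mrow = &moves[(size_t)i * width];
    const char ai = A[i - 1];
    int* prow = prev.data();
    int* crow = cur.data();
    crow[(size_t)(lo - i + band)] = BIG;          // left sentinel for this row
    for (int j = lo; j <= hi; ++j) {
      const int o = j - i + band + 1;
      int best = (j > 0) ? prow[o] + (ai != B[j - 1]) : BIG;
      uint8_t mv = 1;
      const int up = prow[o + 1] + 1;
      if (up < best) { best = up; mv = 2; }
      const int lf = crow[o - 1] + 1;
      if (lf < best) { best = lf; mv = 3; }
      crow[o] = best;
      mrow[(size_t)(o - 1)] = mv;
    }
    crow[(size_t)(hi - i + band + 2)] = BIG;      // right sentinel
    std::swap(prev, cur);
  }
  int off_end = m - n + band;
  if (off_end < 0 || off_end >= width) return false;
  int d = prev[(size_t)off_end + 1];
  if (d >= BIG || d > band) return false;   // band may have clipped the optimum
  // traceback
  std::string ops;
  ops.reserve((size_t)std::max(n, m) + 8);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t mv;
    if (i == 0) mv = 3;
    else if (j == 0) mv = 2;
    else mv = moves[(size_t)i * width + (size_t)(j - i + band)];
    if (mv == 1)      { ops.push_back(A[i - 1] == B[j - 1] ? 'M' : 'X'); --i; --j; }
    else if (mv == 2) { ops.push_back('D'); --i; }
    else              { ops.push_back('I'); --j; }
  }
  std::reverse(ops.begin(), ops.end());
  *out_dist = d; *out_ops = ops;
  return true;
}

static void banded_tb(const char* A, int n, const char* B, int m, int band0,
                      long* dist, std::string* ops) {
  int band = std::max(band0, std::abs(n - m) + 8);
  for (;;) {
    if (banded_tb_try(A, n, B, m, band, dist, ops)) return;
    band *= 2;
    if (band > std::max(n, m) + 1) band = std::max(n, m) + 1;
  }
}

// Global alignment of two strings; returns dist, cols, transcript.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, int band = 64) {
  long d; std::string ops;
  banded_tb(a.data(), (int)a.size(), b.data(), (int)b.size(), band, &d, &ops);
  return List::create(_["dist"] = (double)d, _["cols"] = (double)ops.size(),
                      _["transcript"] = ops);
}

// ---------------------------------------------------------------------------
// Blockwise extension
// ---------------------------------------------------------------------------

struct BlockRec { int t_off; int t_len; int c_len; long edits; long cols; };

struct ExtRes {
  int tadv = 0, cadv = 0;
  long edits = 0, cols = 0;
  bool stopped = false;
  std::string ops;
  std::vector<BlockRec> prof;
};

// mode: 0 distance-only, 1 transcript, 2 per-block profile
static ExtRes extend_dir(const char* T, int tlen, const char* C, int clen,
                         int block, int slack, double max_err, int mode) {
  ExtRes r;
  int ti = 0, ci = 0;
  for (;;) {
    int rt = tlen - ti, rc = clen - ci;
    if (rt <= 0 || rc <= 0) break;
    bool swapped = false;
    const char *P, *X; int n, w;
    if (rc < std::min(block, rt)) {
      // candidate side is the short one; consume it fully instead
      swapped = true;
      n = std::min(block, rc); w = std::min(n + slack, rt);
      P = C + ci; X = T + ti;
    } else {
      n = std::min(block, rt); w = std::min(n + slack, rc);
      P = T + ti; X = C + ci;
    }
    long d; int jend;
    myers_core(P, n, X, w, true, &d, &jend);
    long cols = (n + jend + d + 1) / 2;
    if (cols <= 0) cols = 1;
    // per-block error against the shorter of the two aligned pieces: with a
    // free text end a garbage block scores ~0.5 per pattern base only by
    // under-consuming text, so d/min(n, jend) cleanly separates garbage
    // (~0.7) from a noisy-but-real block pair (~0.3)
    double err = (double)d / (double)std::max(1, std::min(n, jend));
    if (err > max_err) { r.stopped = true; break; }
    if (mode == 1) {
      long d2; std::string opsblk;
      banded_tb(P, n, X, jend, (int)d + 8, &d2, &opsblk);
      if (swapped)
        for (char& c : opsblk) { if (c == 'D') c = 'I'; else if (c == 'I') c = 'D'; }
      d = d2; cols = (long)opsblk.size();
      r.ops += opsblk;
    }
    int tadv = swapped ? jend : n;
    int cadv = swapped ? n : jend;
    if (mode == 2) r.prof.push_back({ti, tadv, cadv, d, cols});
    r.edits += d; r.cols += cols;
    ti += tadv; ci += cadv;
    if (tadv == 0 && cadv == 0) break;
  }
  r.tadv = ti; r.cadv = ci;
  return r;
}

// [[Rcpp::export]]
List cpp_block_align(std::string tpl, std::string cand, int seed_t, int seed_c,
                     int block = 500, int slack = 250, double max_err = 0.5,
                     std::string mode = "dist") {
  int tlen = (int)tpl.size(), clen = (int)cand.size();
  if (seed_t < 0 || seed_t > tlen || seed_c < 0 || seed_c > clen)
    stop("seed outside the reads");
  int imode = (mode == "tb") ? 1 : (mode == "profile" ? 2 : 0);
  // left: reverse the prefixes
  std::string tr(tpl.rbegin() + (tlen - seed_t), tpl.rbegin() + tlen);
  std::string cr(cand.rbegin() + (clen - seed_c), cand.rbegin() + clen);
  ExtRes left = extend_dir(tr.data(), seed_t, cr.data(), seed_c,
                           block, slack, max_err, imode);
  ExtRes right = extend_dir(tpl.data() + seed_t, tlen - seed_t,
                            cand.data() + seed_c, clen - seed_c,
                            block, slack, max_err, imode);
  long edits = left.edits + right.edits;
  long cols = left.cols + right.cols;
  std::string ops(left.ops.rbegin(), left.ops.rend());
  ops += right.ops;
  List out = List::create(
    _["t_start"] = seed_t - left.tadv, _["t_end"] = seed_t + right.tadv,
    _["c_start"] = seed_c - left.cadv, _["c_end"] = seed_c + right.cadv,
    _["edits"] = (double)edits, _["cols"] = (double)cols,
    _["diff"] = cols > 0 ? (double)edits / (double)cols : 1.0,
    _["stopped_left"] = left.stopped, _["stopped_right"] = right.stopped);
  if (imode == 1) out["transcript"] = ops;
  if (imode == 2) {
    int nl = (int)left.prof.size(), nr = (int)right.prof.size();
    IntegerVector t_off(nl + nr), t_len(nl + nr), c_len(nl + nr);
    NumericVector bedits(nl + nr), bcols(nl + nr);
    int idx = 0;
    for (int i = nl - 1; i >= 0; --i, ++idx) {   // left blocks, genome order
      const BlockRec& b = left.prof[(size_t)i];
      t_off[idx] = seed_t - b.t_off - b.t_len; t_len[idx] = b.t_len;
      c_len[idx] = b.c_len;
      bedits[idx] = (double)b.edits; bcols[idx] = (double)b.cols;
    }
    for (int i = 0; i < nr; ++i, ++idx) {
      const BlockRec& b = right.prof[(size_t)i];
      t_off[idx] = seed_t + b.t_off; t_len[idx] = b.t_len;
      c_len[idx] = b.c_len;
      bedits[idx] = (double)b.edits; bcols[idx] = (double)b.cols;
    }
    out["blocks"] = DataFrame::create(_["t_off"] = t_off, _["t_len"] = t_len,
                                      _["c_len"] = c_len,
                                      _["edits"] = bedits, _["cols"] = bcols);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Anchor chaining (gap-tolerant, for the sensitive aligner and mapping)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_anchor_chain(std::string a, std::string b, int k = 11,
                               int stride = 2, int max_anchors = 1500,
                               double gap_frac = 0.4, int gap_slop = 200) {
  int na = (int)a.size(), nb = (int)b.size();
  std::vector<std::pair<int, int>> match;
  if (na >= k && nb >= k) {
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::unordered_multimap<uint64_t, int> tab;
    tab.reserve((size_t)(nb / stride + 16));
    uint64_t code = 0;
    for (int i = 0; i < nb; ++i) {
      code = ((code << 2) | (uint64_t)base_code(b[i])) & mask;
      int p = i - k + 1;
      if (p >= 0 && p % stride == 0) tab.emplace(code, p);
    }
    code = 0;
    for (int i = 0; i < na; ++i) {
      code = ((code << 2) | (uint64_t)base_code(a[i])) & mask;
      int p = i - k + 1;
      if (p >= 0 && p % stride == 0) {
        auto rng = tab.equal_range(code);
        for (auto it = rng.first; it != rng.second; ++it)
          match.emplace_back(p, it->second);
      }
    }
  }
  if ((int)match.size() > max_anchors) {
    std::vector<std::pair<int, int>> sub;
    double step = (double)match.size() / max_anchors;
    for (int i = 0; i < max_anchors; ++i) sub.push_back(match[(size_t)(i * step)]);
    match.swap(sub);
  }
  std::sort(match.begin(), match.end());
  int n = (int)match.size();
  if (n == 0) return IntegerMatrix(0, 2);
  std::vector<int> f(n, 1), pre(n, -1);
  int besti = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i - 1; j >= 0; --j) {
      if (match[j].first >= match[i].first) continue;
      if (match[j].second >= match[i].second) continue;
      int dt = match[i].first - match[j].first;
      int dc = match[i].second - match[j].second;
      int lim = (int)(gap_frac * std::max(dt, dc)) + gap_slop;
      if (std::abs(dt - dc) > lim) continue;
      if (f[j] + 1 > f[i]) { f[i] = f[j] + 1; pre[i] = j; }
    }
    if (f[i] > f[besti]) besti = i;
  }
  std::vector<int> path;
  for (int i = besti; i != -1; i = pre[i]) path.push_back(i);
  std::reverse(path.begin(), path.end());
  IntegerMatrix out((int)path.size(), 2);
  for (int i = 0; i < (int)path.size(); ++i) {
    out(i, 0) = match[(size_t)path[(size_t)i]].first;
    out(i, 1) = match[(size_t)path[(size_t)i]].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sensitive aligner: coarse anchor chain, exact alignment of the chained
// interval, blockwise extension beyond the terminal anchors.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RObject cpp_sensitive_align(std::string tpl, std::string cand, int k = 11,
                            int stride = 2, double max_diff = 0.5,
                            int block = 500, int slack = 250,
                            int min_anchors = 4) {
  IntegerMatrix ch = cpp_anchor_chain(tpl, cand, k, stride);
  int n = ch.nrow();
  if (n < min_anchors) return R_NilValue;
  long edits = 0;
  std::string ops;
  int a0 = ch(0, 0), b0 = ch(0, 1);
  for (int i = 1; i < n; ++i) {
    int ga = ch(i, 0) - ch(i - 1, 0), gb = ch(i, 1) - ch(i - 1, 1);
    long d; std::string seg;
    banded_tb(tpl.data() + ch(i - 1, 0), ga, cand.data() + ch(i - 1, 1), gb,
              std::max(32, std::abs(ga - gb) + 32), &d, &seg);
    edits += d; ops += seg;
  }
  // final anchor k-mer
  int alast = ch(n - 1, 0), blast = ch(n - 1, 1);
  int ktail = std::min({k, (int)tpl.size() - alast, (int)cand.size() - blast});
  ops.append((size_t)ktail, 'M');
  // extend outward
  ExtRes right = extend_dir(tpl.data() + alast + ktail,
                            (int)tpl.size() - alast - ktail,
                            cand.data() + blast + ktail,
                            (int)cand.size() - blast - ktail,
                            block, slack, 0.5, 1);
  std::string tr(tpl.rbegin() + ((int)tpl.size() - a0), tpl.rbegin() + tpl.size());
  std::string cr(cand.rbegin() + ((int)cand.size() - b0), cand.rbegin() + cand.size());
  ExtRes left = extend_dir(tr.data(), a0, cr.data(), b0, block, slack, 0.5, 1);
  std::string lops(left.ops.rbegin(), left.ops.rend());
  ops = lops + ops + right.ops;
  edits += left.edits + right.edits;
  long cols = (long)ops.size();
  double diff = cols > 0 ? (double)edits / (double)cols : 1.0;
  if (diff > max_diff) return R_NilValue;
  return List::create(
    _["t_start"] = a0 - left.tadv, _["t_end"] = alast + ktail + right.tadv,
    _["c_start"] = b0 - left.cadv, _["c_end"] = blast + ktail + right.cadv,
    _["edits"] = (double)edits, _["cols"] = (double)cols, _["diff"] = diff,
    _["stopped_left"] = left.stopped, _["stopped_right"] = right.stopped,
    _["transcript"] = ops);
}
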