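// Low-level sequence kernels: 2-bit k-mer indexing, banded global/fitting
// alignment with traceback, X-drop end extension, a seed-and-extend toy read
// mapper (short fitting mode / long anchor-chain mode) and CIGAR pileup.
// All coordinates are 0-based half-open; CIGARs are SAM-style with the
// assembly as reference (M consumes both, I consumes read, D consumes ref,
// S soft-clips read).
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cstdlib>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string rc(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = comp(s[i]);
  return out;
}

// iterate valid k-mers of s, calling f(pos, code)
template <typename F>
static void for_kmers(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int v = b2i(s[i]);
    if (v < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)v) & mask;
    if (++run >= k) f((int)(i + 1 - k), code);
  }
}

// ---------------------------------------------------------------------------
// k-mer matching between two sequences (anchors for chaining)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_kmer_matches(std::string a, std::string b, int k, int max_occ) {
  std::unordered_map<uint64_t, std::vector<int> > bpos;
  std::unordered_map<uint64_t, int> bcount, acount;
  bpos.reserve(b.size());
  for_kmers(b, k, [&](int pos, uint64_t code) {
    int& c = bcount[code];
    ++c;
    if (c <= max_occ) bpos[code].push_back(pos);
  });
  for_kmers(a, k, [&](int, uint64_t code) { ++acount[code]; });
  std::vector<int> av, bv;
  for_kmers(a, k, [&](int pos, uint64_t code) {
    if (acount[code] > max_occ) return;
    auto it = bcount.find(code);
    if (it == bcount.end() || it->second > max_occ) return;
    for (int bp : bpos[code]) { av.push_back(pos); bv.push_back(bp); }
  });
  return DataFrame::create(_["apos"] = av, _["bpos"] = bv);
}

// consecutive-occurrence spacings of repeated k-mers within one sequence;
// used for large-period tandem-array detection
// [[Rcpp::export]]
DataFrame cpp_kmer_self_spacings(std::string s, int k, int min_d, int max_d,
                                 int max_occ) {
  std::unordered_map<uint64_t, std::vector<int> > occ;
  occ.reserve(s.size());
  for_kmers(s, k, [&](int pos, uint64_t code) {
    std::vector<int>& v = occ[code];
    if ((int)v.size() <= max_occ) v.push_back(pos);
  });
  std::vector<int> pv, dv;
  for (auto& kv : occ) {
    const std::vector<int>& v = kv.second;
    if (v.size() < 2 || (int)v.size() > max_occ) continue;
    for (size_t i = 1; i < v.size(); ++i) {
      int d = v[i] - v[i - 1];
      if (d >= min_d && d <= max_d) { pv.push_back(v[i - 1]); dv.push_back(d); }
    }
  }
  return DataFrame::create(_["pos"] = pv, _["d"] = dv);
}

// match vector at lag d: out[i] = (s[from+i] == s[from+i+d]) for from+i+d < to
// [[Rcpp::export]]
LogicalVector cpp_lag_matches(std::string s, int d, int from, int to) {
  int n = std::max(0, to - from - d);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (s[from + i] == s[from + i + d]);
  return out;
}

// ---------------------------------------------------------------------------
// small-period tandem array scan (periods min_p..max_p, typically <= 64)
// ---------------------------------------------------------------------------
// For each period p, positions where s[i] == s[i+p] are scanned; maximal
// runs are merged across short mismatch gaps while the purity bound holds.
// [[Rcpp::export]]
DataFrame cpp_small_period_arrays(std::string s, int min_p, int max_p,
                                  double min_copies, double min_purity) {
  int n = (int)s.size();
  std::vector<int> st, en, per, mis;
  for (int p = min_p; p <= max_p; ++p) {
    if (2 * p >= n) break;
    int i = 0;
    int L = n - p;
    while (i < L) {
      if (s[i] != s[i + p]) { ++i; continue; }
      // start of a run of lag-p matches; extend with gap merging
      int start = i;
      int match = 0, mismatch = 0;
      int j = i;
      int last_match_end = i;
      int tail_run = 0;
      while (j < L) {
        if (s[j] == s[j + p]) {
          ++match; ++tail_run; last_match_end = j + 1; ++j; continue;
        }
        // lookahead: resume within maxgap positions, and only if a near
        // full unit of matches flanks the gap on BOTH sides (so chance
        // matches next to an array cannot pull its boundary outward)
        int need = std::max(2, p - 1);
        if (tail_run < need) break;
        int maxgap = std::max(2, p / 4);
        int g = 1;
        while (g <= maxgap && j + g < L && s[j + g] != s[j + g + p]) ++g;
        if (g > maxgap || j + g >= L) break;
        int run = 0;
        while (run < need && j + g + run < L &&
               s[j + g + run] == s[j + g + run + p]) ++run;
        if (run < need) break;
        // check purity if we absorb the gap
        int span_if = (j + g) - start + p;
        if ((double)(mismatch + g) / span_if > (1.0 - min_purity)) break;
        mismatch += g;
        j += g;
        tail_run = 0;
      }
      int end = last_match_end + p;       // array spans one extra period
      int span = end - start;
      double purity = 1.0 - (double)mismatch / span;
      if (span >= (int)(min_copies * p) && purity >= min_purity &&
          match >= p) {
        st.push_back(start); en.push_back(end);
        per.push_back(p); mis.push_back(mismatch);
      }
      i = last_match_end + 1;
    }
  }
  return DataFrame::create(_["start"] = st, _["end"] = en,
                           _["period"] = per, _["mismatch"] = mis);
}

// ---------------------------------------------------------------------------
// banded global alignment with traceback
// ---------------------------------------------------------------------------

struct AlnResult {
  int edit, nmis, ngap, columns;
  std::string cigar;
  int a_used, b_used;  // for extension mode
  int score;
  int fit_start;       // for fitting mode: start offset in a (the reference)
};

static void push_op(std::string& cig, char op, int len) {
  if (len <= 0) return;
  cig += std::to_string(len);
  cig += op;
}

static const int BIG = 1 << 28;

// global banded alignment, a = reference, b = read/query.
// ops: M both, D consumes a, I consumes b.
static AlnResult ga_global(const std::string& a, const std::string& b,
                           int band) {
  int n = (int)a.size(), m = (int)b.size();
  AlnResult res; res.a_used = n; res.b_used = m; res.fit_start = 0; res.score = 0;
  if (n == 0 || m == 0) {
    res.edit = n + m; res.nmis = 0; res.ngap = n + m; res.columns = n + m;
    res.cigar = "";
    if (n > 0) push_op(res.cigar, 'D', n);
    if (m > 0) push_op(res.cigar, 'I', m);
    return res;
  }
  int lo = std::min(0, m - n) - band;
  int hi = std::max(0, m - n) + band;
  int w = hi - lo + 1;
  std::vector<int> dp((size_t)(n + 1) * w, BIG);
  std::vector<uint8_t> tb((size_t)(n + 1) * w, 255);
  auto idx = [&](int i, int c) { return (size_t)i * w + c; };
  for (int c = 0; c < w; ++c) {
    int j = lo + c;
    if (j >= 0 && j <= m) { dp[idx(0, c)] = j; tb[idx(0, c)] = 1; }
  }
  for (int i = 1; i <= n; ++i) {
    for (int c = 0; c < w; ++c) {
      int j = i + lo + c;
      if (j < 0 || j > m) continue;
      int best = BIG; uint8_t op = 255;
      if (j >= 1) {
        int v = dp[idx(i - 1, c)];
        if (v < BIG) {
          v += (a[i - 1] == b[j - 1]) ? 0 : 1;
          if (v < best) { best = v; op = 0; }
        }
      }
      if (c + 1 < w) {            // from (i-1, j): gap in b, consumes a -> D
        int v = dp[idx(i - 1, c + 1)];
        if (v < BIG && v + 1 < best) { best = v + 1; op = 2; }
      }
      if (c - 1 >= 0 && j >= 1) { // from (i, j-1): gap in a, consumes b -> I
        int v = dp[idx(i, c - 1)];
        if (v < BIG && v + 1 < best) { best = v + 1; op = 1; }
      }
      dp[idx(i, c)] = best; tb[idx(i, c)] = op;
    }
  }
  int cend = m - n - lo;
  res.edit = dp[idx(n, cend)];
  // traceback; among co-optimal predecessors prefer extending the current
  // gap (consolidates indels into contiguous blocks), then M, then D/I
  std::vector<std::pair<char, int> > ops;
  int i = n, c = cend;
  int nmis = 0, ngap = 0, cols = 0;
  auto add = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  char last = 0;
  while (i > 0 || (i + lo + c) > 0) {
    int j = i + lo + c;
    int cur = dp[idx(i, c)];
    bool canM = i >= 1 && j >= 1 && dp[idx(i - 1, c)] < BIG &&
      dp[idx(i - 1, c)] + ((a[i - 1] == b[j - 1]) ? 0 : 1) == cur;
    bool canD = i >= 1 && c + 1 < w && dp[idx(i - 1, c + 1)] < BIG &&
      dp[idx(i - 1, c + 1)] + 1 == cur;
    bool canI = c >= 1 && j >= 1 && dp[idx(i, c - 1)] < BIG &&
      dp[idx(i, c - 1)] + 1 == cur;
    char op;
    if (last == 'I' && canI) op = 'I';
    else if (last == 'D' && canD) op = 'D';
    else if (canM) op = 'M';
    else if (canD) op = 'D';
    else if (canI) op = 'I';
    else break;
    if (op == 'M') {
      add('M'); ++cols;
      if (a[i - 1] != b[j - 1]) ++nmis;
      --i;
    } else if (op == 'D') { add('D'); ++cols; ++ngap; --i; ++c; }
    else { add('I'); ++cols; ++ngap; --c; }
    last = op;
  }
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  for (auto& o : ops) push_op(cig, o.first, o.second);
  res.cigar = cig; res.nmis = nmis; res.ngap = ngap; res.columns = cols;
  return res;
}

// fitting alignment: all of b (read) aligned inside a (reference window);
// a-start and a-end are free.
static AlnResult ga_fit(const std::string& a, const std::string& b, int band) {
  int n = (int)a.size(), m = (int)b.size();
  // rows over b (read), cols over a; offset c = (j - i) with j index in a
  int lo = -band;
  int hi = (n - m) + band;
  if (hi < lo) hi = lo;
  int w = hi - lo + 1;
  std::vector<int> dp((size_t)(m + 1) * w, BIG);
  std::vector<uint8_t> tb((size_t)(m + 1) * w, 255);
  auto idx = [&](int i, int c) { return (size_t)i * w + c; };
  for (int c = 0; c < w; ++c) {
    int j = lo + c;
    if (j >= 0 && j <= n) { dp[idx(0, c)] = 0; tb[idx(0, c)] = 3; } // free start
  }
  for (int i = 1; i <= m; ++i) {
    for (int c = 0; c < w; ++c) {
      int j = i + lo + c;
      if (j < 0 || j > n) continue;
      int best = BIG; uint8_t op = 255;
      if (j >= 1) {
        int v = dp[idx(i - 1, c)];
        if (v < BIG) {
          v += (a[j - 1] == b[i - 1]) ? 0 : 1;
          if (v < best) { best = v; op = 0; }
        }
      }
      // gap in a (read base unmatched by ref) = I : from (i-1, j) -> c+1
      if (c + 1 < w) {
        int v = dp[idx(i - 1, c + 1)];
        if (v < BIG && v + 1 < best) { best = v + 1; op = 1; }
      }
      // gap in b (ref base skipped) = D : from (i, j-1) -> c-1
      if (c - 1 >= 0 && j >= 1) {
        int v = dp[idx(i, c - 1)];
        if (v < BIG && v + 1 < best) { best = v + 1; op = 2; }
      }
      dp[idx(i, c)] = best; tb[idx(i, c)] = op;
    }
  }
  // free end: min over last row
  int bestc = -1, bestv = BIG;
  for (int c = 0; c < w; ++c) {
    int j = m + lo + c;
    if (j < 0 || j > n) continue;
    if (dp[idx(m, c)] < bestv) { bestv = dp[idx(m, c)]; bestc = c; }
  }
  AlnResult res; res.score = 0;
  if (bestc < 0) { res.edit = BIG; res.cigar = ""; res.fit_start = 0;
    res.nmis = 0; res.ngap = 0; res.columns = 0; res.a_used = 0; res.b_used = m;
    return res; }
  res.edit = bestv;
  std::vector<std::pair<char, int> > ops;
  auto add = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  int i = m, c = bestc;
  int nmis = 0, ngap = 0, cols = 0;
  int jend = m + lo + bestc;
  while (i > 0) {
    uint8_t op = tb[idx(i, c)];
    int j = i + lo + c;
    if (op == 0) { add('M'); ++cols; if (a[j - 1] != b[i - 1]) ++nmis; --i; }
    else if (op == 1) { add('I'); ++cols; ++ngap; --i; ++c; }
    else if (op == 2) { add('D'); ++cols; ++ngap; --c; }
    else break;
  }
  int jstart = i + lo + c;
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  for (auto& o : ops) push_op(cig, o.first, o.second);
  res.cigar = cig; res.nmis = nmis; res.ngap = ngap; res.columns = cols;
  res.fit_start = jstart; res.a_used = jend - jstart; res.b_used = m;
  return res;
}

// X-drop style extension of b (read tail) along a (reference segment),
// both starting at offset 0; returns best-scoring partial alignment.
static AlnResult ga_extend(const std::string& a, const std::string& b,
                           int band) {
  const int MATCH = 1, MIS = -2, GAP = -3;
  int n = (int)a.size(), m = (int)b.size();
  AlnResult res; res.fit_start = 0;
  if (n == 0 || m == 0) {
    res.edit = 0; res.nmis = 0; res.ngap = 0; res.columns = 0;
    res.cigar = ""; res.a_used = 0; res.b_used = 0; res.score = 0;
    return res;
  }
  int lo = -band, hi = band; int w = hi - lo + 1;
  const int NEG = -(1 << 28);
  std::vector<int> dp((size_t)(m + 1) * w, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * w, 255);
  auto idx = [&](int i, int c) { return (size_t)i * w + c; };
  dp[idx(0, -lo)] = 0;
  for (int c = -lo + 1; c < w; ++c) {  // leading ref gaps (rare)
    int j = lo + c;
    if (j <= n) { dp[idx(0, c)] = GAP * j; tb[idx(0, c)] = 2; }
  }
  int besti = 0, bestc = -lo, bestv = 0;
  for (int i = 1; i <= m; ++i) {
    int rowbest = NEG;
    for (int c = 0; c < w; ++c) {
      int j = i + lo + c;
      if (j < 0 || j > n) continue;
      int best = NEG; uint8_t op = 255;
      if (j >= 1) {
        int v = dp[idx(i - 1, c)];
        if (v > NEG) {
          v += (a[j - 1] == b[i - 1]) ? MATCH : MIS;
          if (v > best) { best = v; op = 0; }
        }
      }
      if (c + 1 < w) {
        int v = dp[idx(i - 1, c + 1)];
        if (v > NEG && v + GAP > best) { best = v + GAP; op = 1; } // I
      }
      if (c - 1 >= 0 && j >= 1) {
        int v = dp[idx(i, c - 1)];
        if (v > NEG && v + GAP > best) { best = v + GAP; op = 2; } // D
      }
      if (op == 255) continue;
      dp[idx(i, c)] = best; tb[idx(i, c)] = op;
      if (best > rowbest) rowbest = best;
      if (best > bestv) { bestv = best; besti = i; bestc = c; }
    }
    if (rowbest < bestv - 100) break;  // X-drop
  }
  // traceback from best cell
  std::vector<std::pair<char, int> > ops;
  auto add = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  int i = besti, c = bestc;
  int nmis = 0, ngap = 0, cols = 0, edit = 0;
  while (i > 0 || (i + lo + c) > 0) {
    uint8_t op = tb[idx(i, c)];
    if (op == 255) break;
    int j = i + lo + c;
    if (op == 0) { add('M'); ++cols; if (a[j - 1] != b[i - 1]) { ++nmis; ++edit; } --i; }
    else if (op == 1) { add('I'); ++cols; ++ngap; ++edit; --i; ++c; }
    else if (op == 2) { add('D'); ++cols; ++ngap; ++edit; --c; }
    else break;
  }
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  for (auto& o : ops) push_op(cig, o.first, o.second);
  res.cigar = cig; res.nmis = nmis; res.ngap = ngap; res.columns = cols;
  res.edit = edit; res.a_used = besti + lo + bestc; res.b_used = besti;
  res.score = bestv;
  return res;
}

// indices (1-based) of a longest strictly-increasing subsequence of v
// [[Rcpp::export]]
IntegerVector cpp_lis(IntegerVector v) {
  int n = v.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tail_idx;            // index of smallest tail per length
  std::vector<int> prev(n, -1);
  std::vector<int> tails;
  for (int i = 0; i < n; ++i) {
    int x = v[i];
    int lo = (int)(std::lower_bound(tails.begin(), tails.end(), x) -
                   tails.begin());
    if (lo == (int)tails.size()) { tails.push_back(x); tail_idx.push_back(i); }
    else { tails[lo] = x; tail_idx[lo] = i; }
    prev[i] = lo > 0 ? tail_idx[lo - 1] : -1;
  }
  std::vector<int> out;
  for (int i = tail_idx.back(); i >= 0; i = prev[i]) out.push_back(i + 1);
  std::reverse(out.begin(), out.end());
  return wrap(out);
}

// fitting alignment of b (query) inside a (window): free window start/end
// [[Rcpp::export]]
List cpp_fit_align(std::string a, std::string b, int band) {
  AlnResult r = ga_fit(a, b, band);
  return List::create(_["edit"] = r.edit, _["a_start"] = r.fit_start,
                      _["a_end"] = r.fit_start + r.a_used,
                      _["cigar"] = r.cigar);
}

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int band) {
  AlnResult r = ga_global(a, b, band);
  return List::create(_["edit"] = r.edit, _["n_mismatch"] = r.nmis,
                      _["n_gap_columns"] = r.ngap, _["columns"] = r.columns,
                      _["cigar"] = r.cigar);
}

// ---------------------------------------------------------------------------
// read mapper
// ---------------------------------------------------------------------------

struct RefIndex {
  std::vector<std::string> seqs;
  std::vector<long long> offsets;       // cumulative start of each contig
  long long total;
  std::unordered_map<uint64_t, std::vector<long long> > pos;  // capped
  std::unordered_map<uint64_t, int> count;
  int k;
  int contig_of(long long g) const {
    int c = (int)(std::upper_bound(offsets.begin(), offsets.end(), g) -
                  offsets.begin()) - 1;
    return c;
  }
};

static void build_index(RefIndex& ix, const std::vector<std::string>& seqs,
                        int k, int max_keep) {
  ix.seqs = seqs; ix.k = k;
  ix.offsets.clear();
  long long off = 0;
  for (auto& s : seqs) { ix.offsets.push_back(off); off += (long long)s.size(); }
  ix.total = off;
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    long long base = ix.offsets[ci];
    for_kmers(seqs[ci], k, [&](int p, uint64_t code) {
      int& c = ix.count[code];
      ++c;
      if (c <= max_keep) ix.pos[code].push_back(base + p);
    });
  }
}

struct MapHit {
  bool mapped = false;
  std::string status = "unmapped";
  int contig = -1;
  int ref_start = 0, ref_end = 0;
  char strand = '+';
  int edit = 0;
  std::string cigar;
};

static uint64_t encode_kmer(const std::string& s, int off, int k, bool& ok) {
  uint64_t code = 0; ok = true;
  for (int i = 0; i < k; ++i) {
    int v = b2i(s[off + i]);
    if (v < 0) { ok = false; return 0; }
    code = (code << 2) | (uint64_t)v;
  }
  return code;
}

static MapHit map_short_one(const RefIndex& ix, const std::string& read,
                            int band, double max_edit_frac) {
  int k = ix.k, L = (int)read.size();
  MapHit hit;
  if (L < k) { hit.status = "too_short"; return hit; }
  std::string rcread = rc(read);
  struct Cand { char strand; long long gstart; };
  std::vector<Cand> cands;
  int seed_offs[3] = {0, L / 2, L - k};
  for (int st = 0; st < 2; ++st) {
    const std::string& s = st == 0 ? read : rcread;
    for (int so = 0; so < 3; ++so) {
      int off = seed_offs[so];
      bool ok; uint64_t code = encode_kmer(s, off, k, ok);
      if (!ok) continue;
      auto it = ix.count.find(code);
      if (it == ix.count.end() || it->second > 16) continue;
      for (long long g : ix.pos.at(code)) {
        cands.push_back({st == 0 ? '+' : '-', g - off});
      }
    }
  }
  if (cands.empty()) { hit.status = "no_seed"; return hit; }
  std::sort(cands.begin(), cands.end(), [](const Cand& x, const Cand& y) {
    if (x.strand != y.strand) return x.strand < y.strand;
    return x.gstart < y.gstart;
  });
  std::vector<Cand> uniq;
  for (auto& c : cands) {
    if (!uniq.empty() && uniq.back().strand == c.strand &&
        c.gstart - uniq.back().gstart <= 3) continue;
    uniq.push_back(c);
    if (uniq.size() >= 32) break;
  }
  int best = BIG, second = BIG;
  AlnResult bestr; Cand bestc{'+', 0}; long long best_wstart = 0; int bestci = -1;
  for (auto& c : uniq) {
    int ci = ix.contig_of(std::min(std::max(c.gstart, (long long)0),
                                   ix.total - 1));
    const std::string& ref = ix.seqs[ci];
    long long cstart = ix.offsets[ci];
    long long ws = c.gstart - cstart - 4;
    long long we = ws + L + 8;
    if (ws < 0) ws = 0;
    if (we > (long long)ref.size()) we = ref.size();
    if (we - ws < k) continue;
    std::string window = ref.substr((size_t)ws, (size_t)(we - ws));
    const std::string& q = c.strand == '+' ? read : rcread;
    AlnResult r = ga_fit(window, q, band);
    if (r.edit < best) {
      second = best; best = r.edit; bestr = r; bestc = c;
      best_wstart = ws; bestci = ci;
    } else if (r.edit < second) second = r.edit;
  }
  if (bestci < 0 || best > (int)(max_edit_frac * L)) {
    hit.status = "poor"; return hit;
  }
  if (second == best) { hit.status = "ambiguous"; return hit; }
  hit.mapped = true; hit.status = "mapped";
  hit.contig = bestci;
  hit.ref_start = (int)(best_wstart + bestr.fit_start);
  hit.ref_end = hit.ref_start + bestr.a_used;
  hit.strand = bestc.strand;
  hit.edit = best;
  hit.cigar = bestr.cigar;
  return hit;
}

struct Anchor { int rpos; long long gpos; };

static MapHit map_long_one(const RefIndex& ix, const std::string& read,
                           int ext_max) {
  int k = ix.k, L = (int)read.size();
  MapHit hit;
  if (L < k) { hit.status = "too_short"; return hit; }
  std::string rcread = rc(read);
  // collect unique-in-reference anchors for both strands, cluster by diagonal
  struct Cluster { char strand; std::vector<Anchor> anchors; };
  std::vector<Cluster> clusters;
  size_t best_so_far = 0;
  for (int st = 0; st < 2; ++st) {
    // if the forward strand already anchors most of the read, the reverse
    // strand cannot compete (anchors are reference-unique)
    if (st == 1 && best_so_far > 0.3 * (L - k + 1)) break;
    const std::string& s = st == 0 ? read : rcread;
    std::vector<std::pair<long long, Anchor> > da;  // (diag, anchor)
    for_kmers(s, k, [&](int p, uint64_t code) {
      auto it = ix.count.find(code);
      if (it == ix.count.end() || it->second != 1) return;
      long long g = ix.pos.at(code)[0];
      da.push_back(std::make_pair(g - p, Anchor{p, g}));
    });
    if (da.empty()) continue;
    std::sort(da.begin(), da.end(),
              [](const std::pair<long long, Anchor>& x,
                 const std::pair<long long, Anchor>& y) {
                return x.first < y.first;
              });
    size_t i0 = 0;
    for (size_t i = 1; i <= da.size(); ++i) {
      if (i == da.size() || da[i].first - da[i - 1].first > 400) {
        Cluster cl; cl.strand = st == 0 ? '+' : '-';
        for (size_t j = i0; j < i; ++j) cl.anchors.push_back(da[j].second);
        if (cl.anchors.size() > best_so_far) best_so_far = cl.anchors.size();
        clusters.push_back(cl);
        i0 = i;
      }
    }
  }
  if (clusters.empty()) { hit.status = "no_anchor"; return hit; }
  std::sort(clusters.begin(), clusters.end(),
            [](const Cluster& a, const Cluster& b) {
              return a.anchors.size() > b.anchors.size();
            });
  if (clusters[0].anchors.size() < 3) { hit.status = "no_anchor"; return hit; }
  if (clusters.size() > 1 &&
      clusters[1].anchors.size() == clusters[0].anchors.size()) {
    hit.status = "ambiguous"; return hit;
  }
  Cluster& cl = clusters[0];
  const std::string& q = cl.strand == '+' ? read : rcread;
  std::sort(cl.anchors.begin(), cl.anchors.end(),
            [](const Anchor& a, const Anchor& b) { return a.rpos < b.rpos; });
  // keep anchors monotone in gpos and within one contig (majority contig)
  int ci = ix.contig_of(cl.anchors[cl.anchors.size() / 2].gpos);
  long long cstart = ix.offsets[ci];
  long long cend = cstart + (long long)ix.seqs[ci].size();
  std::vector<Anchor> chain;
  for (auto& a : cl.anchors) {
    if (a.gpos < cstart || a.gpos + k > cend) continue;
    if (!chain.empty() && a.gpos <= chain.back().gpos) continue;
    if (!chain.empty() && a.rpos < chain.back().rpos + 1) continue;
    chain.push_back(a);
  }
  if (chain.size() < 2) { hit.status = "no_anchor"; return hit; }
  const std::string& ref = ix.seqs[ci];
  // build alignment piecewise
  std::string cigar;
  int edit = 0;
  // head extension (left of first anchor)
  int r0 = chain[0].rpos;
  long long g0 = chain[0].gpos - cstart;
  int head_take = std::min(r0, ext_max);
  long long hstart = std::max((long long)0, g0 - head_take - 64);
  std::string ha(ref.rbegin() + (ref.size() - g0),
                 ref.rbegin() + (ref.size() - hstart));
  std::string hb(q.rbegin() + (L - r0), q.rbegin() + (L - (r0 - head_take)));
  int hband = 48 + head_take / 40;
  AlnResult hr = ga_extend(ha, hb, hband);
  long long ref_start = g0 - hr.a_used;
  int read_aln_start = r0 - hr.b_used;
  edit += hr.edit;
  std::string headcig;
  {
    // reverse cigar ops of hr
    std::vector<std::pair<char, int> > ops;
    int num = 0;
    for (char ch : hr.cigar) {
      if (ch >= '0' && ch <= '9') num = num * 10 + (ch - '0');
      else { ops.push_back(std::make_pair(ch, num)); num = 0; }
    }
    std::reverse(ops.begin(), ops.end());
    for (auto& o : ops) push_op(headcig, o.first, o.second);
  }
  if (read_aln_start > 0) {
    std::string sc; push_op(sc, 'S', read_aln_start);
    cigar += sc;
  }
  cigar += headcig;
  // anchors + gaps
  int r = r0; long long g = g0;  // aligned-through positions (exclusive ends set below)
  int mrun = 0;
  auto flush_m = [&]() { if (mrun > 0) { push_op(cigar, 'M', mrun); mrun = 0; } };
  // first anchor
  mrun += k; r = r0 + k; g = g0 + k;
  for (size_t ai = 1; ai < chain.size(); ++ai) {
    int ri = chain[ai].rpos;
    long long gi = chain[ai].gpos - cstart;
    if (ri < r || gi < g) continue;  // overlapping/contained anchor
    long long gap_g = gi - g;
    int gap_r = ri - r;
    if (gap_r == 0 && gap_g == 0) { mrun += k; }
    else if (gap_r == (int)gap_g && gap_r <= 64) {
      // equal-length gap: count mismatches directly
      for (int t = 0; t < gap_r; ++t)
        if (ref[(size_t)(g + t)] != q[(size_t)(r + t)]) ++edit;
      mrun += gap_r + k;
    } else {
      long long cells = (long long)(gap_g + 1) *
        (2 * (std::llabs(gap_g - gap_r) + 16) + 1);
      if (std::max((long long)gap_r, gap_g) > 20000 || cells > 40000000) {
        // approximate: match the shorter side, gap the difference
        flush_m();
        long long mn = std::min((long long)gap_r, gap_g);
        if (mn > 0) push_op(cigar, 'M', (int)mn);
        if (gap_g > mn) { push_op(cigar, 'D', (int)(gap_g - mn)); edit += (int)(gap_g - mn); }
        if (gap_r > mn) { push_op(cigar, 'I', (int)(gap_r - mn)); edit += (int)(gap_r - mn); }
        mrun = k;
      } else {
        std::string ga = ref.substr((size_t)g, (size_t)gap_g);
        std::string gb = q.substr((size_t)r, (size_t)gap_r);
        AlnResult br = ga_global(ga, gb, 16);
        edit += br.edit;
        flush_m();
        cigar += br.cigar;
        mrun = k;
      }
    }
    r = ri + k; g = gi + k;
  }
  flush_m();
  // tail extension
  int tail_take = std::min(L - r, ext_max);
  long long tend = std::min(cend - cstart, g + tail_take + 64);
  std::string ta = ref.substr((size_t)g, (size_t)(tend - g));
  std::string tbq = q.substr((size_t)r, (size_t)tail_take);
  int tband = 48 + tail_take / 40;
  AlnResult tr = ga_extend(ta, tbq, tband);
  edit += tr.edit;
  cigar += tr.cigar;
  long long ref_end = g + tr.a_used;
  int read_aln_end = r + tr.b_used;
  if (L - read_aln_end > 0) push_op(cigar, 'S', L - read_aln_end);
  hit.mapped = true; hit.status = "mapped";
  hit.contig = ci;
  hit.ref_start = (int)ref_start;
  hit.ref_end = (int)ref_end;
  hit.strand = cl.strand;
  hit.edit = edit;
  hit.cigar = cigar;
  return hit;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector ref_seqs, CharacterVector read_seqs,
                        std::string mode, int k, int band,
                        double max_edit_frac, int ext_max) {
  std::vector<std::string> refs;
  for (int i = 0; i < ref_seqs.size(); ++i)
    refs.push_back(as<std::string>(ref_seqs[i]));
  RefIndex ix;
  build_index(ix, refs, k, mode == "short" ? 16 : 1);
  int n = read_seqs.size();
  IntegerVector contig(n), rstart(n), rend(n), edit(n);
  CharacterVector strand(n), cigar(n), status(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(read_seqs[i]);
    MapHit h = mode == "short" ? map_short_one(ix, rd, band, max_edit_frac)
                               : map_long_one(ix, rd, ext_max);
    if (h.mapped && h.edit > (int)(max_edit_frac * rd.size())) {
      h.mapped = false; h.status = "poor";
    }
    contig[i] = h.mapped ? h.contig + 1 : NA_INTEGER;
    rstart[i] = h.mapped ? h.ref_start : NA_INTEGER;
    rend[i] = h.mapped ? h.ref_end : NA_INTEGER;
    edit[i] = h.mapped ? h.edit : NA_INTEGER;
    strand[i] = std::string(1, h.strand);
    cigar[i] = h.cigar;
    status[i] = h.status;
  }
  return DataFrame::create(_["contig_idx"] = contig, _["ref_start"] = rstart,
                           _["ref_end"] = rend, _["strand"] = strand,
                           _["edit"] = edit, _["cigar"] = cigar,
                           _["status"] = status,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// pileup from CIGAR alignments
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pileup(CharacterVector ref_seqs, IntegerVector contig_idx,
                IntegerVector ref_start, CharacterVector strand,
                CharacterVector cigar, CharacterVector read_seqs) {
  int nc = ref_seqs.size();
  std::vector<std::string> refs;
  std::vector<IntegerMatrix> counts;
  for (int c = 0; c < nc; ++c) {
    refs.push_back(as<std::string>(ref_seqs[c]));
    counts.push_back(IntegerMatrix(5, (int)refs[c].size()));
  }
  std::map<std::pair<int, int>, std::map<std::string, int> > ins;
  int n = contig_idx.size();
  for (int i = 0; i < n; ++i) {
    if (IntegerVector::is_na(contig_idx[i])) continue;
    int ci = contig_idx[i] - 1;
    std::string rd = as<std::string>(read_seqs[i]);
    if (as<std::string>(strand[i]) == "-") rd = rc(rd);
    std::string cg = as<std::string>(cigar[i]);
    int g = ref_start[i], r = 0;
    IntegerMatrix& cm = counts[ci];
    const std::string& ref = refs[ci];
    int reflen = (int)ref.size();
    int num = 0;
    for (char ch : cg) {
      if (ch >= '0' && ch <= '9') { num = num * 10 + (ch - '0'); continue; }
      int len = num; num = 0;
      if (ch == 'S') { r += len; }
      else if (ch == 'M') {
        for (int t = 0; t < len; ++t) {
          if (g >= 0 && g < reflen) {
            int b = b2i(rd[r]);
            if (b >= 0) cm(b, g) += 1;
          }
          ++g; ++r;
        }
      } else if (ch == 'D') {
        if (len == 1 && g >= 0 && g < reflen) {
          // left-normalise single-base deletions within homopolymer runs so
          // all reads vote on the same column
          int gd = g;
          while (gd > 0 && ref[gd - 1] == ref[g]) --gd;
          cm(4, gd) += 1;
          ++g;
        } else {
          for (int t = 0; t < len; ++t) {
            if (g >= 0 && g < reflen) cm(4, g) += 1;
            ++g;
          }
        }
      } else if (ch == 'I') {
        if (g >= 0 && g <= reflen && len <= 200) {
          // left-normalise the insertion point through repeat context
          std::string X = rd.substr(r, len);
          int ip = g;
          int guard = 0;
          while (ip > 0 && ref[ip - 1] == X[X.size() - 1] && guard < 500) {
            X = X.back() + X.substr(0, X.size() - 1);
            --ip; ++guard;
          }
          if (ip >= 1) ins[std::make_pair(ci, ip - 1)][X] += 1;
        }
        r += len;
      }
    }
  }
  std::vector<int> ic, ip, icount;
  std::vector<std::string> iseq;
  for (auto& kv : ins) {
    for (auto& sv : kv.second) {
      ic.push_back(kv.first.first + 1);
      ip.push_back(kv.first.second);
      iseq.push_back(sv.first);
      icount.push_back(sv.second);
    }
  }
  List cl(nc);
  for (int c = 0; c < nc; ++c) cl[c] = counts[c];
  return List::create(
    _["counts"] = cl,
    _["insertions"] = DataFrame::create(
      _["contig_idx"] = ic, _["pos"] = ip, _["seq"] = iseq,
      _["count"] = icount, _["stringsAsFactors"] = false));
}
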