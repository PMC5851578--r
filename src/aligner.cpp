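// Seed-and-extend machinery: k-mer indexing, diagonal seed chaining and
// banded affine-gap local alignment. Coordinates here are 0-based
// half-open; the R layer converts to 1-based closed GRanges coordinates.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char compBase(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// forward and reverse-complement k-mer codes for every start position;
// UINT32_MAX marks windows containing non-ACGT characters
static void kmerCodes(const char *s, int64_t L, int k,
                      std::vector<uint32_t> &fwd, std::vector<uint32_t> &rc) {
  int64_t n = L - k + 1;
  if (n < 1) { fwd.clear(); rc.clear(); return; }
  fwd.assign(n, UINT32_MAX);
  rc.assign(n, UINT32_MAX);
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  uint32_t f = 0, r = 0;
  int run = 0;  // number of consecutive valid bases ending at current pos
  for (int64_t i = 0; i < L; ++i) {
    int c = baseCode(s[i]);
    if (c < 0) {
      run = 0; f = 0; r = 0;
      continue;
    }
    f = ((f << 2) | (uint32_t)c) & mask;
    r = (r >> 2) | ((uint32_t)(3 - c) << (2 * (k - 1)));
    ++run;
    if (run >= k) {
      fwd[i - k + 1] = f;
      rc[i - k + 1] = r;
    }
  }
}

// occurrence index: positions bucketed by code (counting sort)
struct KIndex {
  std::vector<int32_t> off;  // size 4^k + 1
  std::vector<int32_t> pos;  // positions sorted by code
};

static void buildIndex(const std::vector<uint32_t> &codes, int k, KIndex &ix) {
  size_t ncode = ((size_t)1) << (2 * k);
  ix.off.assign(ncode + 1, 0);
  int32_t nvalid = 0;
  for (size_t i = 0; i < codes.size(); ++i)
    if (codes[i] != UINT32_MAX) { ++ix.off[codes[i] + 1]; ++nvalid; }
  for (size_t c = 1; c <= ncode; ++c) ix.off[c] += ix.off[c - 1];
  ix.pos.assign(nvalid, 0);
  std::vector<int32_t> cur(ix.off.begin(), ix.off.end() - 1);
  for (size_t i = 0; i < codes.size(); ++i)
    if (codes[i] != UINT32_MAX) ix.pos[cur[codes[i]]++] = (int32_t)i;
}

struct Chain {
  int64_t a_first, a_last;   // k-mer start positions on a
  int64_t b_min, b_max;      // k-mer start positions on b
  int64_t d_min, d_max;      // diagonal (same) or anti-diagonal (opposite)
  int n;
  int orient;                // 0 same, 1 opposite
};

struct ChainSink {
  std::vector<int64_t> a_start, a_end, b_start, b_end, d_min, d_max;
  std::vector<int> nseeds, orient;
  int k;
  // gates applied at flush time so low-quality chains never leave C++
  int min_seeds;
  double min_density;
  int64_t min_span;
  void flush(const Chain &c) {
    if (c.n < min_seeds) return;
    int64_t span = std::max(c.a_last + k - c.a_first, c.b_max + k - c.b_min);
    if (span < min_span) return;
    if ((double)c.n / (double)std::max(span - k + 1, (int64_t)1) < min_density)
      return;
    a_start.push_back(c.a_first);
    a_end.push_back(c.a_last + k);
    b_start.push_back(c.b_min);
    b_end.push_back(c.b_max + k);
    d_min.push_back(c.d_min);
    d_max.push_back(c.d_max);
    nseeds.push_back(c.n);
    orient.push_back(c.orient);
  }
};

typedef std::unordered_map<int64_t, Chain> ChainMap;

static inline void chainHit(ChainMap &m, ChainSink &sink, int64_t key,
                            int64_t a, int64_t b, int64_t d, int orient,
                            int max_gap) {
  ChainMap::iterator it = m.find(key);
  if (it == m.end()) {
    Chain c = {a, a, b, b, d, d, 1, orient};
    m.emplace(key, c);
    return;
  }
  Chain &c = it->second;
  if (a - c.a_last > max_gap) {
    sink.flush(c);
    c.a_first = a; c.a_last = a; c.b_min = b; c.b_max = b;
    c.d_min = d; c.d_max = d; c.n = 1;
  } else {
    c.a_last = a;
    if (b < c.b_min) c.b_min = b;
    if (b > c.b_max) c.b_max = b;
    if (d < c.d_min) c.d_min = d;
    if (d > c.d_max) c.d_max = d;
    ++c.n;
  }
}

static inline int64_t floorDiv(int64_t x, int64_t y) {
  int64_t q = x / y, r = x % y;
  return (r != 0 && ((r < 0) != (y < 0))) ? q - 1 : q;
}

static DataFrame sinkToDf(ChainSink &sink) {
  size_t n = sink.a_start.size();
  NumericVector as(n), ae(n), bs(n), be(n), dmin(n), dmax(n);
  IntegerVector ns(n), ori(n);
  for (size_t i = 0; i < n; ++i) {
    as[i] = (double)sink.a_start[i]; ae[i] = (double)sink.a_end[i];
    bs[i] = (double)sink.b_start[i]; be[i] = (double)sink.b_end[i];
    dmin[i] = (double)sink.d_min[i]; dmax[i] = (double)sink.d_max[i];
    ns[i] = sink.nseeds[i]; ori[i] = sink.orient[i];
  }
  return DataFrame::create(_["a_start"] = as, _["a_end"] = ae,
                           _["b_start"] = bs, _["b_end"] = be,
                           _["d_min"] = dmin, _["d_max"] = dmax,
                           _["nseeds"] = ns, _["orient"] = ori);
}

// All-vs-all self seed chains on one (concatenated) sequence. Every shared
// k-mer between two positions (both orientations) is a seed; seeds are
// grouped by (orientation, diagonal bucket) and split on gaps > max_gap.
// Each position pairs with at most max_occ following occurrences of its
// k-mer, which preserves single-linkage connectivity for high-copy repeats.
// [[Rcpp::export]]
DataFrame cpp_self_seed_chains(std::string seq, int k, int band_width,
                               int max_gap, int max_occ, int min_seeds,
                               double min_density, int min_span) {
  if (k < 4 || k > 14) stop("seed k must be in [4, 14]");
  if ((int64_t)seq.size() > INT32_MAX - 2) stop("sequence too long");
  int64_t L = (int64_t)seq.size();
  std::vector<uint32_t> fwd, rc;
  kmerCodes(seq.c_str(), L, k, fwd, rc);
  KIndex fix, rix;
  buildIndex(fwd, k, fix);
  buildIndex(rc, k, rix);

  ChainMap same_m, opp_m;
  ChainSink sink; sink.k = k;
  sink.min_seeds = min_seeds; sink.min_density = min_density;
  sink.min_span = min_span;
  int64_t bw = band_width;
  int64_t n = (int64_t)fwd.size();
  for (int64_t a = 0; a < n; ++a) {
    uint32_t c = fwd[a];
    if (c == UINT32_MAX) continue;
    // same orientation: occurrences of c after a
    {
      int32_t lo = fix.off[c], hi = fix.off[c + 1];
      const int32_t *base = fix.pos.data();
      const int32_t *it = std::upper_bound(base + lo, base + hi, (int32_t)a);
      int taken = 0;
      for (; it != base + hi && taken < max_occ; ++it, ++taken) {
        int64_t b = *it;
        int64_t d = b - a;
        int64_t key = (floorDiv(d, bw) << 1);
        chainHit(same_m, sink, key, a, b, d, 0, max_gap);
      }
    }
    // opposite orientation: positions b > a whose reverse complement is c
    {
      int32_t lo = rix.off[c], hi = rix.off[c + 1];
      const int32_t *base = rix.pos.data();
      const int32_t *it = std::upper_bound(base + lo, base + hi, (int32_t)a);
      int taken = 0;
      for (; it != base + hi && taken < max_occ; ++it, ++taken) {
        int64_t b = *it;
        int64_t d = a + b;  // anti-diagonal
        int64_t key = (floorDiv(d, bw) << 1) | 1;
        chainHit(opp_m, sink, key, a, b, d, 1, max_gap);
      }
    }
  }
  for (ChainMap::iterator it = same_m.begin(); it != same_m.end(); ++it)
    sink.flush(it->second);
  for (ChainMap::iterator it = opp_m.begin(); it != opp_m.end(); ++it)
    sink.flush(it->second);
  return sinkToDf(sink);
}

// Seed chains of one query sequence against an indexed genome (both
// orientations). a_* coordinates are on the query, b_* on the genome.
// [[Rcpp::export]]
DataFrame cpp_cross_seed_chains(std::string query, std::string genome, int k,
                                int band_width, int max_gap, int min_seeds,
                                double min_density, int min_span) {
  if (k < 4 || k > 14) stop("seed k must be in [4, 14]");
  if ((int64_t)genome.size() > INT32_MAX - 2) stop("sequence too long");
  std::vector<uint32_t> qf, qr, gf, gr;
  kmerCodes(query.c_str(), (int64_t)query.size(), k, qf, qr);
  kmerCodes(genome.c_str(), (int64_t)genome.size(), k, gf, gr);
  KIndex fix, rix;
  buildIndex(gf, k, fix);
  buildIndex(gr, k, rix);

  ChainMap same_m, opp_m;
  ChainSink sink; sink.k = k;
  sink.min_seeds = min_seeds; sink.min_density = min_density;
  sink.min_span = min_span;
  int64_t bw = band_width;
  int64_t n = (int64_t)qf.size();
  for (int64_t a = 0; a < n; ++a) {
    uint32_t c = qf[a];
    if (c == UINT32_MAX) continue;
    {
      int32_t lo = fix.off[c], hi = fix.off[c + 1];
      for (int32_t t = lo; t < hi; ++t) {
        int64_t b = fix.pos[t];
        int64_t d = b - a;
        int64_t key = (floorDiv(d, bw) << 1);
        chainHit(same_m, sink, key, a, b, d, 0, max_gap);
      }
    }
    {
      int32_t lo = rix.off[c], hi = rix.off[c + 1];
      for (int32_t t = lo; t < hi; ++t) {
        int64_t b = rix.pos[t];
        int64_t d = a + b;
        int64_t key = (floorDiv(d, bw) << 1) | 1;
        chainHit(opp_m, sink, key, a, b, d, 1, max_gap);
      }
    }
  }
  for (ChainMap::iterator it = same_m.begin(); it != same_m.end(); ++it)
    sink.flush(it->second);
  for (ChainMap::iterator it = opp_m.begin(); it != opp_m.end(); ++it)
    sink.flush(it->second);
  return sinkToDf(sink);
}

// ---------------------------------------------------------------------------
// Banded local alignment, affine gaps, full traceback.
// Band constraint: d_lo <= j - i <= d_hi over 1-based DP indices.

struct AlnResult {
  int score, matches, columns;
  int64_t a_start, a_end, b_start, b_end;  // 0-based half-open
  bool ok;
};

static const int NEG_INF = -1000000000;

static AlnResult bandedLocal(const char *a, int na, const char *b, int nb,
                             int d_lo, int d_hi, int match, int mismatch,
                             int gap_open, int gap_extend) {
  AlnResult res; res.ok = false; res.score = 0;
  if (d_lo > d_hi || na < 1 || nb < 1) return res;
  if (d_lo < 1 - na) d_lo = 1 - na;
  if (d_hi > nb - 1) d_hi = nb - 1;
  if (d_lo > d_hi) return res;
  int W = d_hi - d_lo + 1;

  std::vector<int> Hprev(W, 0), Hcur(W, 0), Eprev(W, NEG_INF),
      Ecur(W, NEG_INF), Fprev(W, NEG_INF), Fcur(W, NEG_INF);
  // traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 E=gap in a-row?,
  // 3 F), bit 2 E opened here, bit 3 F opened here
  std::vector<uint8_t> tb((size_t)(na + 1) * W, 0);

  int best = 0, best_i = 0, best_w = 0;
  for (int i = 1; i <= na; ++i) {
    for (int w = 0; w < W; ++w) { Hcur[w] = 0; Ecur[w] = NEG_INF; Fcur[w] = NEG_INF; }
    for (int w = 0; w < W; ++w) {
      int j = i + d_lo + w;
      if (j < 1 || j > nb) { Hcur[w] = (j == 0) ? 0 : NEG_INF; continue; }
      uint8_t t = 0;
      // E: gap in a (consumes b): predecessor (i, j-1) -> same row, w-1
      int e = NEG_INF;
      if (w - 1 >= 0) {
        int open = (Hcur[w - 1] > NEG_INF / 2) ? Hcur[w - 1] + gap_open : NEG_INF;
        int ext = (Ecur[w - 1] > NEG_INF / 2) ? Ecur[w - 1] + gap_extend : NEG_INF;
        if (open >= ext) { e = open; t |= 4; } else e = ext;
      }
      Ecur[w] = e;
      // F: gap in b (consumes a): predecessor (i-1, j) -> row i-1, w+1
      int f = NEG_INF;
      if (w + 1 < W) {
        int open = (Hprev[w + 1] > NEG_INF / 2) ? Hprev[w + 1] + gap_open : NEG_INF;
        int ext = (Fprev[w + 1] > NEG_INF / 2) ? Fprev[w + 1] + gap_extend : NEG_INF;
        if (open >= ext) { f = open; t |= 8; } else f = ext;
      }
      Fcur[w] = f;
      // H: diag predecessor (i-1, j-1) -> row i-1, same w
      int diag = NEG_INF;
      int hp = Hprev[w];
      if (hp > NEG_INF / 2)
        diag = hp + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      int h = 0; int src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hcur[w] = h;
      t |= (uint8_t)src;
      tb[(size_t)i * W + w] = t;
      if (h > best) { best = h; best_i = i; best_w = w; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  if (best <= 0) return res;

  // traceback
  int i = best_i, w = best_w;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  int matches = 0, columns = 0;
  int end_i = best_i, end_j = best_i + d_lo + best_w;
  int start_i = end_i, start_j = end_j;
  while (i > 0) {
    int j = i + d_lo + w;
    uint8_t t = tb[(size_t)i * W + w];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ++columns;
        if (a[i - 1] == b[j - 1]) ++matches;
        start_i = i; start_j = j;
        i -= 1;  // w unchanged on diagonal move
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // E: consumed b[j-1], move to (i, j-1)
      ++columns;
      start_j = j;
      bool opened = (t & 4) != 0;
      w -= 1;
      state = opened ? 0 : 1;
    } else {  // F: consumed a[i-1], move to (i-1, j)
      ++columns;
      start_i = i;
      bool opened = (t & 8) != 0;
      i -= 1; w += 1;
      state = opened ? 0 : 2;
    }
  }
  res.ok = true;
  res.score = best;
  res.matches = matches;
  res.columns = columns;
  res.a_start = start_i - 1; res.a_end = end_i;
  res.b_start = start_j - 1; res.b_end = end_j;
  return res;
}

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int d_lo, int d_hi,
                      int match, int mismatch, int gap_open, int gap_extend) {
  AlnResult r = bandedLocal(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(),
                            d_lo, d_hi, match, mismatch, gap_open, gap_extend);
  return List::create(_["ok"] = r.ok, _["score"] = r.score,
                      _["matches"] = r.matches, _["columns"] = r.columns,
                      _["a_start"] = (double)r.a_start, _["a_end"] = (double)r.a_end,
                      _["b_start"] = (double)r.b_start, _["b_end"] = (double)r.b_end);
}

static std::string revComp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = compBase(r[i]);
  return r;
}

// Extend seed chains within one sequence (self-alignment). Chains carry
// 0-based coordinates from cpp_self_seed_chains. Returns alignments passing
// min_len (both images) and min_ident; all coordinates forward-strand,
// 0-based half-open.
// [[Rcpp::export]]
DataFrame cpp_extend_self_chains(std::string seq, NumericVector a_start,
                                 NumericVector a_end, NumericVector b_start,
                                 NumericVector b_end, IntegerVector orient,
                                 NumericVector d_min, NumericVector d_max,
                                 int k, int band_width, int flank, int match,
                                 int mismatch, int gap_open, int gap_extend,
                                 int min_len, double min_ident) {
  int64_t L = (int64_t)seq.size();
  int nch = a_start.size();
  std::vector<double> oas, oae, obs, obe, oid;
  std::vector<int> osc, omat, ocol, oori;
  for (int c = 0; c < nch; ++c) {
    int64_t was = std::max((int64_t)0, (int64_t)a_start[c] - flank);
    int64_t wae = std::min(L, (int64_t)a_end[c] + flank);
    int64_t wbs = std::max((int64_t)0, (int64_t)b_start[c] - flank);
    int64_t wbe = std::min(L, (int64_t)b_end[c] + flank);
    if (wae - was < min_len || wbe - wbs < min_len) continue;
    std::string astr = seq.substr(was, wae - was);
    std::string bstr;
    int d_lo, d_hi;
    if (orient[c] == 0) {
      bstr = seq.substr(wbs, wbe - wbs);
      d_lo = (int)((int64_t)d_min[c] - (wbs - was)) - band_width;
      d_hi = (int)((int64_t)d_max[c] - (wbs - was)) + band_width;
    } else {
      bstr = revComp(seq.substr(wbs, wbe - wbs));
      int64_t C = wbe - k + was;
      d_lo = (int)(C - (int64_t)d_max[c]) - band_width;
      d_hi = (int)(C - (int64_t)d_min[c]) + band_width;
    }
    AlnResult r = bandedLocal(astr.c_str(), (int)astr.size(), bstr.c_str(),
                              (int)bstr.size(), d_lo, d_hi, match, mismatch,
                              gap_open, gap_extend);
    if (!r.ok) continue;
    int64_t ga_s = was + r.a_start, ga_e = was + r.a_end;
    int64_t gb_s, gb_e;
    if (orient[c] == 0) { gb_s = wbs + r.b_start; gb_e = wbs + r.b_end; }
    else { gb_s = wbe - r.b_end; gb_e = wbe - r.b_start; }
    if (ga_e - ga_s < min_len || gb_e - gb_s < min_len) continue;
    double ident = (double)r.matches / (double)r.columns;
    if (ident < min_ident) continue;
    oas.push_back((double)ga_s); oae.push_back((double)ga_e);
    obs.push_back((double)gb_s); obe.push_back((double)gb_e);
    oid.push_back(ident); osc.push_back(r.score);
    omat.push_back(r.matches); ocol.push_back(r.columns);
    oori.push_back(orient[c]);
  }
  return DataFrame::create(_["a_start"] = oas, _["a_end"] = oae,
                           _["b_start"] = obs, _["b_end"] = obe,
                           _["identity"] = oid, _["score"] = osc,
                           _["matches"] = omat, _["columns"] = ocol,
                           _["orient"] = oori);
}

// Extend cross (query-vs-genome) seed chains. a coordinates on query,
// b on genome.
// [[Rcpp::export]]
DataFrame cpp_extend_cross_chains(std::string query, std::string genome,
                                  NumericVector a_start, NumericVector a_end,
                                  NumericVector b_start, NumericVector b_end,
                                  IntegerVector orient, NumericVector d_min,
                                  NumericVector d_max, int k, int band_width,
                                  int flank, int match, int mismatch,
                                  int gap_open, int gap_extend, int min_len,
                                  double min_ident) {
  int64_t La = (int64_t)query.size(), Lb = (int64_t)genome.size();
  int nch = a_start.size();
  std::vector<double> oas, oae, obs, obe, oid;
  std::vector<int> osc, omat, ocol, oori;
  for (int c = 0; c < nch; ++c) {
    int64_t was = std::max((int64_t)0, (int64_t)a_start[c] - flank);
    int64_t wae = std::min(La, (int64_t)a_end[c] + flank);
    int64_t wbs = std::max((int64_t)0, (int64_t)b_start[c] - flank);
    int64_t wbe = std::min(Lb, (int64_t)b_end[c] + flank);
    if (wae - was < min_len || wbe - wbs < min_len) continue;
    std::string astr = query.substr(was, wae - was);
    std::string bstr;
    int d_lo, d_hi;
    if (orient[c] == 0) {
      bstr = genome.substr(wbs, wbe - wbs);
      d_lo = (int)((int64_t)d_min[c] - (wbs - was)) - band_width;
      d_hi = (int)((int64_t)d_max[c] - (wbs - was)) + band_width;
    } else {
      bstr = revComp(genome.substr(wbs, wbe - wbs));
      int64_t C = wbe - k + was;
      d_lo = (int)(C - (int64_t)d_max[c]) - band_width;
      d_hi = (int)(C - (int64_t)d_min[c]) + band_width;
    }
    AlnResult r = bandedLocal(astr.c_str(), (int)astr.size(), bstr.c_str(),
                              (int)bstr.size(), d_lo, d_hi, match, mismatch,
                              gap_open, gap_extend);
    if (!r.ok) continue;
    int64_t ga_s = was + r.a_start, ga_e = was + r.a_end;
    int64_t gb_s, gb_e;
    if (orient[c] == 0) { gb_s = wbs + r.b_start; gb_e = wbs + r.b_end; }
    else { gb_s = wbe - r.b_end; gb_e = wbe - r.b_start; }
    if (ga_e - ga_s < min_len || gb_e - gb_s < min_len) continue;
    double ident = (double)r.matches / (double)r.columns;
    if (ident < min_ident) continue;
    oas.push_back((double)ga_s); oae.push_back((double)ga_e);
    obs.push_back((double)gb_s); obe.push_back((double)gb_e);
    oid.push_back(ident); osc.push_back(r.score);
    omat.push_back(r.matches); ocol.push_back(r.columns);
    oori.push_back(orient[c]);
  }
  return DataFrame::create(_["a_start"] = oas, _["a_end"] = oae,
                           _["b_start"] = obs, _["b_end"] = obe,
                           _["identity"] = oid, _["score"] = osc,
                           _["matches"] = omat, _["columns"] = ocol,
                           _["orient"] = oori);
}
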