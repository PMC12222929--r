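// Alignment and clustering primitives.
// All interval coordinates returned to R are 0-based half-open.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// ---------------------------------------------------------------------------
// Local alignment (Smith-Waterman, linear gap penalty) with traceback.
// Returns best local alignment: score, identity (matches / columns),
// span (alignment columns), and 0-based half-open intervals on a and b.
struct AlnRes {
  double score; double identity; int span;
  int a_start, a_end, b_start, b_end;
  int matches;
  std::string a_aln, b_aln;
};

static AlnRes sw_local(const std::string& a, const std::string& b,
                       double match, double mismatch, double gap,
                       bool keep_aln) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnRes res; res.score = 0; res.identity = 0; res.span = 0;
  res.a_start = res.a_end = res.b_start = res.b_end = 0; res.matches = 0;
  if (n == 0 || m == 0) return res;
  if ((double)(n + 1) * (m + 1) > 6e8)
    stop("sequences too long for full DP (%d x %d); use banded alignment", n, m);
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  // dir: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<uint8_t> dir((size_t)(n + 1) * (m + 1), 0);
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    uint8_t* di = &dir[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + ((base2code(ai) >= 0 &&
                                     toupper(ai) == toupper(b[j - 1]))
                                    ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double s = sdiag; uint8_t d = 1;
      if (sup > s) { s = sup; d = 2; }
      if (sleft > s) { s = sleft; d = 3; }
      if (s <= 0) { s = 0; d = 0; }
      cur[j] = s; di[j] = d;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  res.score = best;
  if (best <= 0) return res;
  // traceback
  int i = bi, j = bj, matches = 0, cols = 0;
  std::string aa, bb;
  while (i > 0 && j > 0) {
    uint8_t d = dir[(size_t)i * (m + 1) + j];
    if (d == 0) break;
    if (d == 1) {
      if (toupper(a[i - 1]) == toupper(b[j - 1])) ++matches;
      if (keep_aln) { aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); }
      --i; --j; ++cols;
    } else if (d == 2) {
      if (keep_aln) { aa.push_back(a[i - 1]); bb.push_back('-'); }
      --i; ++cols;
    } else {
      if (keep_aln) { aa.push_back('-'); bb.push_back(b[j - 1]); }
      --j; ++cols;
    }
  }
  res.a_start = i; res.a_end = bi; res.b_start = j; res.b_end = bj;
  res.span = cols; res.matches = matches;
  res.identity = cols > 0 ? (double)matches / cols : 0.0;
  if (keep_aln) { std::reverse(aa.begin(), aa.end()); std::reverse(bb.begin(), bb.end());
                  res.a_aln = aa; res.b_aln = bb; }
  return res;
}

static List aln_to_list(const AlnRes& r, bool keep_aln) {
  List out = List::create(
    _["score"] = r.score, _["identity"] = r.identity, _["span"] = r.span,
    _["matches"] = r.matches,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end);
  if (keep_aln) { out["a_aln"] = r.a_aln; out["b_aln"] = r.b_aln; }
  return out;
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, double match = 1,
                     double mismatch = -1, double gap = -2,
                     bool keep_aln = false) {
  return aln_to_list(sw_local(a, b, match, mismatch, gap, keep_aln), keep_aln);
}

// Banded local alignment around diagonal d0 (j - i = d0 +/- band).
static AlnRes sw_banded(const std::string& a, const std::string& b,
                        int d0, int band, double match, double mismatch,
                        double gap, bool keep_aln) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = 2 * band + 1;
  AlnRes res; res.score = 0; res.identity = 0; res.span = 0;
  res.a_start = res.a_end = res.b_start = res.b_end = 0; res.matches = 0;
  if (n == 0 || m == 0) return res;
  // score/dir stored as [i][k], k = j - i - d0 + band in [0, W)
  std::vector<double> prev(W, 0.0), cur(W, 0.0);
  std::vector<uint8_t> dir((size_t)(n + 1) * W, 0);
  double best = 0; int bi = 0, bk = 0;
  for (int k = 0; k < W; ++k) prev[k] = 0;
  for (int i = 1; i <= n; ++i) {
    uint8_t* di = &dir[(size_t)i * W];
    for (int k = 0; k < W; ++k) {
      int j = i + d0 - band + k;
      cur[k] = 0; di[k] = 0;
      if (j < 1 || j > m) continue;
      double sdiag = prev[k] + (toupper(a[i - 1]) == toupper(b[j - 1]) &&
                                base2code(a[i - 1]) >= 0 ? match : mismatch);
      double s = sdiag; uint8_t d = 1;
      if (k + 1 < W) { double sup = prev[k + 1] + gap; if (sup > s) { s = sup; d = 2; } }
      if (k - 1 >= 0) { double sleft = cur[k - 1] + gap; if (sleft > s) { s = sleft; d = 3; } }
      if (s <= 0) { s = 0; d = 0; }
      cur[k] = s; di[k] = d;
      if (s > best) { best = s; bi = i; bk = k; }
    }
    std::swap(prev, cur);
  }
  res.score = best;
  if (best <= 0) return res;
  int i = bi, k = bk, matches = 0, cols = 0;
  std::string aa, bb;
  while (i > 0) {
    int j = i + d0 - band + k;
    if (j < 1) break;
    uint8_t d = dir[(size_t)i * W + k];
    if (d == 0) break;
    if (d == 1) {
      if (toupper(a[i - 1]) == toupper(b[j - 1])) ++matches;
      if (keep_aln) { aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); }
      --i; ++cols; // k unchanged (diag keeps offset)
    } else if (d == 2) {
      if (keep_aln) { aa.push_back(a[i - 1]); bb.push_back('-'); }
      --i; ++k; ++cols;
    } else {
      if (keep_aln) { aa.push_back('-'); bb.push_back(b[j - 1]); }
      --k; ++cols;
    }
  }
  int j = i + d0 - band + k;
  res.a_start = i; res.a_end = bi;
  res.b_start = j; res.b_end = bi + d0 - band + bk;
  res.span = cols; res.matches = matches;
  res.identity = cols > 0 ? (double)matches / cols : 0.0;
  if (keep_aln) { std::reverse(aa.begin(), aa.end()); std::reverse(bb.begin(), bb.end());
                  res.a_aln = aa; res.b_aln = bb; }
  return res;
}

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int d0, int band,
                      double match = 1, double mismatch = -1, double gap = -2,
                      bool keep_aln = false) {
  return aln_to_list(sw_banded(a, b, d0, band, match, mismatch, gap, keep_aln),
                     keep_aln);
}

// ---------------------------------------------------------------------------
// Word-match diagonal runs between a and b (both strands), word size <= 32.
// Maximal runs of consecutive matching words (step 1 along a diagonal).
// '-' strand runs are reported with b coordinates on the forward strand.

static void collect_words(const std::string& s, int w,
                          std::vector<std::pair<uint64_t,int>>& out) {
  const int n = (int)s.size();
  uint64_t code = 0, mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++valid >= w) out.emplace_back(code, i - w + 1);
  }
}

static void runs_one_strand(const std::unordered_map<uint64_t,std::vector<int>>& aidx,
                            const std::string& b, int w, char strand,
                            int b_fwd_len,
                            std::vector<int>& a_start, std::vector<int>& b_start,
                            std::vector<int>& len, std::vector<std::string>& str) {
  std::vector<std::pair<uint64_t,int>> bw;
  collect_words(b, w, bw);
  // matches as (diag, bpos, apos)
  std::vector<std::array<int,3>> hits;
  for (auto& pr : bw) {
    auto it = aidx.find(pr.first);
    if (it == aidx.end()) continue;
    for (int ap : it->second) hits.push_back({pr.second - ap, pr.second, ap});
  }
  std::sort(hits.begin(), hits.end());
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i;
    while (j + 1 < hits.size() && hits[j + 1][0] == hits[j][0] &&
           hits[j + 1][1] <= hits[j][1] + 1) ++j;
    int ap = hits[i][2], bp = hits[i][1];
    int L = hits[j][1] - hits[i][1] + w; // bases covered on each sequence
    if (strand == '+') {
      a_start.push_back(ap); b_start.push_back(bp);
    } else {
      // b was reverse-complemented; map interval back to forward coords
      a_start.push_back(ap);
      b_start.push_back(b_fwd_len - (bp + L));
    }
    len.push_back(L); str.push_back(std::string(1, strand));
    i = j + 1;
  }
}

// [[Rcpp::export]]
DataFrame cpp_word_runs(std::string a, std::string b, int word = 10,
                        bool both_strands = true) {
  std::vector<std::pair<uint64_t,int>> aw;
  collect_words(a, word, aw);
  std::unordered_map<uint64_t,std::vector<int>> aidx;
  for (auto& pr : aw) aidx[pr.first].push_back(pr.second);
  std::vector<int> a_start, b_start, len;
  std::vector<std::string> strand;
  runs_one_strand(aidx, b, word, '+', (int)b.size(), a_start, b_start, len, strand);
  if (both_strands) {
    std::string brc = revcomp(b);
    runs_one_strand(aidx, brc, word, '-', (int)b.size(), a_start, b_start, len, strand);
  }
  return DataFrame::create(_["a_start"] = a_start, _["b_start"] = b_start,
                           _["length"] = len, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Read clustering: canonical minimizers (k, w) bucket candidate pairs;
// union-find with Smith-Waterman verification at the similar() thresholds.

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[b] = a; }
};

struct MinHit { uint64_t val; int read; int pos; uint8_t orient; };

// canonical minimizers with the position and orientation of the minimal
// k-mer (orient 0: forward strand holds the canonical form; 1: reverse)
static void read_minimizers(const std::string& s, int k, int w,
                            int read_id, std::vector<MinHit>& out) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int shift = 2 * (k - 1);
  struct KM { uint64_t v; int pos; uint8_t o; };
  std::vector<KM> canon;
  uint64_t f = 0, r = 0; int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { valid = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (uint64_t)c) & mask;
    r = (r >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) {
      if (f <= r) canon.push_back({f, i - k + 1, 0});
      else canon.push_back({r, i - k + 1, 1});
    }
  }
  const int nk = (int)canon.size();
  if (nk == 0) return;
  int ww = std::min(w, nk);
  int last = -1;
  for (int i = 0; i + ww <= nk; ++i) {
    int mi = i;
    for (int j = 1; j < ww; ++j) if (canon[i + j].v < canon[mi].v) mi = i + j;
    if (mi != last) {
      out.push_back({canon[mi].v, read_id, canon[mi].pos, canon[mi].o});
      last = mi;
    }
  }
}

// anchored verification: banded alignment around the shared-minimizer
// diagonal, with a full Smith-Waterman fallback for borderline results
static bool verify_anchored(const std::string& a, const std::string& b_oriented,
                            int d0, double min_ident, double min_cov,
                            double match, double mismatch, double gap,
                            const std::string& a_full, const std::string& b_full) {
  int need = (int)std::ceil(min_cov * std::min(a.size(), b_oriented.size()));
  AlnRes r = sw_banded(a, b_oriented, d0, 10, match, mismatch, gap, false);
  if (r.span >= need && r.identity >= min_ident) return true;
  // borderline: near-threshold banded result gets the exact check
  if (r.identity >= min_ident - 0.04 && r.span >= 0.6 * need) {
    AlnRes rf = sw_local(a_full, b_full, match, mismatch, gap, false);
    if (rf.span >= need && rf.identity >= min_ident) return true;
    AlnRes rr = sw_local(a_full, revcomp(b_full), match, mismatch, gap, false);
    return (rr.span >= need && rr.identity >= min_ident);
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector cpp_cluster_reads(CharacterVector reads, int k = 13, int w = 5,
                                double min_ident = 0.90, double min_cov = 0.55,
                                int max_attempts = 12, double match = 1,
                                double mismatch = -1, double gap = -2) {
  const int n = reads.size();
  std::vector<std::string> rs(n), rc(n);
  for (int i = 0; i < n; ++i) {
    rs[i] = as<std::string>(reads[i]);
    rc[i] = revcomp(rs[i]);
  }
  std::vector<MinHit> pairs;
  for (int i = 0; i < n; ++i) read_minimizers(rs[i], k, w, i, pairs);
  std::sort(pairs.begin(), pairs.end(),
            [](const MinHit& a, const MinHit& b) {
              if (a.val != b.val) return a.val < b.val;
              return a.read < b.read;
            });
  UF uf(n);
  std::vector<int> fails(n, 0);
  const int global_fail_cap = 60;
  size_t i = 0;
  while (i < pairs.size()) {
    size_t j = i;
    while (j + 1 < pairs.size() && pairs[j + 1].val == pairs[i].val) ++j;
    for (size_t x = i + 1; x <= j; ++x) {
      const MinHit& hx = pairs[x];
      if (fails[hx.read] >= global_fail_cap) continue;
      int attempts = 0, scanned = 0;
      for (size_t y = x; y-- > i && attempts < max_attempts && scanned < 80;) {
        const MinHit& hy = pairs[y];
        ++scanned;
        if (uf.find(hx.read) == uf.find(hy.read)) break;
        // orient hy's read so the shared k-mer matches forward-forward
        bool same = (hx.orient == hy.orient);
        const std::string& b = same ? rs[hy.read] : rc[hy.read];
        int posy = same ? hy.pos : (int)rs[hy.read].size() - k - hy.pos;
        int d0 = posy - hx.pos;
        if (verify_anchored(rs[hx.read], b, d0, min_ident, min_cov,
                            match, mismatch, gap, rs[hx.read], rs[hy.read])) {
          uf.unite(hx.read, hy.read);
          break;
        }
        ++attempts;
        ++fails[hx.read];
      }
    }
    i = j + 1;
  }
  // relabel components 1..C in order of first appearance
  IntegerVector out(n);
  std::unordered_map<int,int> lab;
  int next = 0;
  for (int x = 0; x < n; ++x) {
    int r = uf.find(x);
    auto it = lab.find(r);
    if (it == lab.end()) { lab[r] = ++next; out[x] = next; }
    else out[x] = it->second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed-and-extend mapping of (short) queries against one reference.
// Best diagonal by k-mer vote on each strand, then local SW of the query
// against a reference window. Returns per query: mapped flag, ref interval
// (0-based half-open), strand, identity, span, score and the query bases in
// reference space (deletions as '-', insertions dropped) for pileup use.

// [[Rcpp::export]]
List cpp_map_reads(std::string ref, CharacterVector reads, int k = 11,
                   double min_ident = 0.90, double min_cov = 0.55,
                   int band = 30, double match = 1, double mismatch = -1,
                   double gap = -2) {
  const int nref = (int)ref.size();
  std::vector<std::pair<uint64_t,int>> rw;
  collect_words(ref, k, rw);
  std::unordered_map<uint64_t,std::vector<int>> ridx;
  for (auto& pr : rw) ridx[pr.first].push_back(pr.second);
  const int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector ref_start(n), ref_end(n), span(n), q_start(n), q_end(n);
  NumericVector identity(n), score(n);
  CharacterVector strand(n), aligned(n);
  for (int q = 0; q < n; ++q) {
    std::string rd = as<std::string>(reads[q]);
    mapped[q] = false; strand[q] = NA_STRING; aligned[q] = NA_STRING;
    ref_start[q] = NA_INTEGER; ref_end[q] = NA_INTEGER;
    q_start[q] = NA_INTEGER; q_end[q] = NA_INTEGER;
    identity[q] = NA_REAL; score[q] = NA_REAL; span[q] = NA_INTEGER;
    double bestsc = -1; AlnRes bestr; char beststr = '+'; int bestoff = 0;
    for (int st = 0; st < 2; ++st) {
      std::string qs = (st == 0) ? rd : revcomp(rd);
      std::vector<std::pair<uint64_t,int>> qw;
      collect_words(qs, k, qw);
      // vote on diagonals (ref_pos - query_pos)
      std::unordered_map<int,int> votes;
      for (auto& pr : qw) {
        auto it = ridx.find(pr.first);
        if (it == ridx.end()) continue;
        for (int rp : it->second) votes[rp - pr.second]++;
      }
      if (votes.empty()) continue;
      // merge votes over nearby diagonals (within band)
      std::vector<std::pair<int,int>> vd(votes.begin(), votes.end());
      std::sort(vd.begin(), vd.end());
      int bi = 0, bv = -1;
      for (size_t x = 0; x < vd.size(); ++x) {
        int tot = 0;
        for (size_t y = x; y < vd.size() && vd[y].first - vd[x].first <= band; ++y)
          tot += vd[y].second;
        if (tot > bv) { bv = tot; bi = (int)x; }
      }
      int d0 = vd[bi].first;
      int w0 = std::max(0, d0 - band);
      int w1 = std::min(nref, d0 + (int)qs.size() + band);
      if (w1 <= w0) continue;
      std::string win = ref.substr(w0, w1 - w0);
      AlnRes r = sw_local(qs, win, match, mismatch, gap, true);
      if (r.score > bestsc) {
        bestsc = r.score; bestr = r; beststr = (st == 0) ? '+' : '-'; bestoff = w0;
      }
    }
    if (bestsc < 0) continue;
    int need = (int)std::ceil(min_cov * std::min((int)rd.size(), nref));
    if (bestr.span < need || bestr.identity < min_ident) continue;
    mapped[q] = true;
    ref_start[q] = bestoff + bestr.b_start;
    ref_end[q] = bestoff + bestr.b_end;
    q_start[q] = bestr.a_start; q_end[q] = bestr.a_end;
    identity[q] = bestr.identity; score[q] = bestr.score; span[q] = bestr.span;
    strand[q] = std::string(1, beststr);
    // project query bases onto reference columns
    std::string proj;
    for (size_t c = 0; c < bestr.b_aln.size(); ++c) {
      if (bestr.b_aln[c] == '-') continue;          // insertion in query: drop
      proj.push_back(bestr.a_aln[c]);               // query base or '-' (deletion)
    }
    aligned[q] = proj;
  }
  return List::create(_["mapped"] = mapped, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["q_start"] = q_start,
                      _["q_end"] = q_end, _["strand"] = strand,
                      _["identity"] = identity, _["span"] = span,
                      _["score"] = score, _["aligned"] = aligned);
}

// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int ref_len, IntegerVector ref_start,
                         CharacterVector aligned) {
  IntegerMatrix counts(5, ref_len); // rows A,C,G,T,-
  for (int i = 0; i < ref_start.size(); ++i) {
    if (ref_start[i] == NA_INTEGER || aligned[i] == NA_STRING) continue;
    std::string s = as<std::string>(aligned[i]);
    int off = ref_start[i];
    for (size_t j = 0; j < s.size(); ++j) {
      int pos = off + (int)j;
      if (pos < 0 || pos >= ref_len) continue;
      int row;
      char c = s[j];
      if (c == '-') row = 4; else { row = base2code(c); if (row < 0) continue; }
      counts(row, pos)++;
    }
  }
  return counts;
}
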