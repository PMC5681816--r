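// Core kernels: k-mer index, seed-and-extend alignment, de Bruijn assembly,
// exact-anchor chaining, pileup accumulation, gap-closing path search.
// All coordinates are 0-based half-open; only the R layer converts for SAM.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- utilities

static inline int base2code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}
static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
  case 'T': return 'A'; case 'N': return 'N';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = revcomp_str(std::string(x[i]));
  }
  return out;
}

// reverse complement of a 2-bit packed k-mer
static inline uint64_t rc_kmer(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

static std::string kmer_to_str(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = CODE2BASE[v & 3ULL]; v >>= 2; }
  return s;
}

// ---------------------------------------------------------------- k-mer index

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // key: 2-bit packed k-mer; value: packed (ref << 32) | (pos << 1) | strand
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
  uint64_t n_fwd = 0, n_rev = 0;
};

static inline uint64_t pack_hit(uint32_t ref, uint32_t pos, int strand) {
  return (static_cast<uint64_t>(ref) << 32) |
         (static_cast<uint64_t>(pos) << 1) | static_cast<uint64_t>(strand);
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    idx->names.push_back(nm.size() ? as<std::string>(nm[r]) : std::to_string(r));
    idx->seqs.push_back(s);
    const int L = static_cast<int>(s.size());
    uint64_t kmer = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = base2code(s[i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | static_cast<uint64_t>(c)) & mask;
      if (++run >= k) {
        uint32_t pos = static_cast<uint32_t>(i - k + 1);
        idx->map[kmer].push_back(pack_hit(r, pos, 0));
        idx->n_fwd++;
        uint64_t rc = rc_kmer(kmer, k);
        idx->map[rc].push_back(pack_hit(r, pos, 1));
        idx->n_rev++;
      }
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP ptr) {
  XPtr<KmerIndex> idx(ptr);
  return List::create(_["k"] = idx->k,
                      _["n_fwd"] = static_cast<double>(idx->n_fwd),
                      _["n_rev"] = static_cast<double>(idx->n_rev),
                      _["n_distinct"] = static_cast<double>(idx->map.size()),
                      _["ref_names"] = wrap(idx->names));
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP ptr, CharacterVector kmers) {
  XPtr<KmerIndex> idx(ptr);
  std::vector<int> qi, ref, pos, strand;
  const uint64_t mask = (idx->k < 32) ? ((1ULL << (2 * idx->k)) - 1ULL) : ~0ULL;
  for (R_xlen_t q = 0; q < kmers.size(); ++q) {
    std::string s = as<std::string>(kmers[q]);
    if (static_cast<int>(s.size()) != idx->k) continue;
    uint64_t v = 0; bool ok = true;
    for (char c : s) { int b = base2code(c); if (b < 0) { ok = false; break; } v = ((v << 2) | b) & mask; }
    if (!ok) continue;
    auto it = idx->map.find(v);
    if (it == idx->map.end()) continue;
    for (uint64_t h : it->second) {
      qi.push_back(q + 1);
      ref.push_back(static_cast<int>(h >> 32) + 1);
      pos.push_back(static_cast<int>((h & 0xFFFFFFFFULL) >> 1));
      strand.push_back(static_cast<int>(h & 1ULL));
    }
  }
  return DataFrame::create(_["kmer"] = qi, _["ref"] = ref, _["pos"] = pos,
                           _["rev"] = strand);
}

// ------------------------------------------------------- banded/window aligner

struct AlnResult {
  int score = 0;
  int qstart = 0, qend = 0;   // aligned query span, 0-based half-open
  int rstart = 0, rend = 0;   // aligned window span
  std::string cigar;          // M/I/D only (clips added by caller)
};

// Gotoh alignment of query q against ref window w.
// local = true : Smith-Waterman local (soft clips allowed).
// local = false: query end-to-end, ref ends free (no clipping).
static AlnResult align_window(const std::string& q, const char* w, int wlen,
                              bool local, int match, int mismatch,
                              int gap_open, int gap_ext) {
  const int m = static_cast<int>(q.size());
  const int NEG = -100000000;
  const int W = wlen + 1;
  std::vector<int> H((m + 1) * W), E((m + 1) * W), F((m + 1) * W);
  std::vector<uint8_t> tb((m + 1) * W);  // bits0-1: H move (0 diag,1 E,2 F,3 stop)
                                         // bit2: E open, bit3: F open
  for (int j = 0; j <= wlen; ++j) {
    H[j] = 0; E[j] = NEG; F[j] = NEG; tb[j] = 3;
  }
  for (int i = 1; i <= m; ++i) {
    int* Hi = &H[i * W]; int* Hp = &H[(i - 1) * W];
    int* Ei = &E[i * W];
    int* Fi = &F[i * W]; int* Fp = &F[(i - 1) * W];
    uint8_t* ti = &tb[i * W];
    // j = 0 column
    Ei[0] = NEG;
    int fo = Hp[0] + gap_open, fe = Fp[0] + gap_ext;
    Fi[0] = std::max(fo, fe);
    ti[0] = 2 | ((fo >= fe) ? 8 : 0);
    Hi[0] = local ? 0 : Fi[0];
    if (local) ti[0] = 3;
    const char qc = q[i - 1];
    for (int j = 1; j <= wlen; ++j) {
      int eo = Hi[j - 1] + gap_open, ee = Ei[j - 1] + gap_ext;
      Ei[j] = std::max(eo, ee);
      int fo2 = Hp[j] + gap_open, fe2 = Fp[j] + gap_ext;
      Fi[j] = std::max(fo2, fe2);
      int sub = (w[j - 1] == qc && qc != 'N') ? match : mismatch;
      int dg = Hp[j - 1] + sub;
      int best = dg; uint8_t mv = 0;
      if (Ei[j] > best) { best = Ei[j]; mv = 1; }
      if (Fi[j] > best) { best = Fi[j]; mv = 2; }
      if (local && best < 0) { best = 0; mv = 3; }
      Hi[j] = best;
      ti[j] = mv | ((eo >= ee) ? 4 : 0) | ((fo2 >= fe2) ? 8 : 0);
    }
  }
  // locate end
  int bi = 0, bj = 0, bs = NEG;
  if (local) {
    for (int i = 1; i <= m; ++i)
      for (int j = 0; j <= wlen; ++j)
        if (H[i * W + j] > bs) { bs = H[i * W + j]; bi = i; bj = j; }
  } else {
    bi = m;
    for (int j = 0; j <= wlen; ++j)
      if (H[m * W + j] > bs) { bs = H[m * W + j]; bj = j; }
  }
  AlnResult res; res.score = bs; res.qend = bi; res.rend = bj;
  // traceback
  std::string ops;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    uint8_t t = tb[i * W + j];
    if (state == 0) {
      uint8_t mv = t & 3;
      if (mv == 3) break;                       // local stop
      if (mv == 0) { ops.push_back('M'); --i; --j; }
      else state = mv;
      if (!local && i == 0 && state == 0) break; // reached free ref start
    } else if (state == 1) {                    // gap consuming ref: D
      ops.push_back('D'); state = (t & 4) ? 0 : 1; --j;
      if (state == 1) { /* continue extension */ }
      if (j < 0) break;
    } else {                                    // gap consuming query: I
      ops.push_back('I'); state = (t & 8) ? 0 : 2; --i;
    }
    if (!local && i == 0) break;
    if (local && state == 0 && (tb[i * W + j] & 3) == 3 && H[i * W + j] == 0) break;
  }
  res.qstart = i; res.rstart = j;
  // compress ops (reversed)
  std::string cig;
  int n = static_cast<int>(ops.size());
  int p = n - 1;
  while (p >= 0) {
    char op = ops[p]; int cnt = 0;
    while (p >= 0 && ops[p] == op) { ++cnt; --p; }
    cig += std::to_string(cnt); cig.push_back(op);
  }
  res.cigar = cig;
  return res;
}

// Map reads against an index. Returns one row per read (best alignment only).
// mode_local: Smith-Waterman with soft clips (fast-local); otherwise query
// end-to-end (sensitive).
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP ptr, CharacterVector reads, bool mode_local,
                        int seed_step = 2, int max_candidates = 4,
                        int band = 16, int match = 2, int mismatch = -3,
                        int gap_open = -5, int gap_ext = -2) {
  XPtr<KmerIndex> idx(ptr);
  const int k = idx->k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  const R_xlen_t n = reads.size();
  IntegerVector out_ref(n), out_pos(n), out_mapq(n), out_score(n);
  LogicalVector out_rev(n), out_unmapped(n);
  CharacterVector out_cigar(n);

  std::unordered_map<uint64_t, int> votes;
  for (R_xlen_t ri = 0; ri < n; ++ri) {
    std::string read = as<std::string>(reads[ri]);
    const int m = static_cast<int>(read.size());
    out_unmapped[ri] = true; out_ref[ri] = NA_INTEGER; out_pos[ri] = NA_INTEGER;
    out_mapq[ri] = 0; out_score[ri] = 0; out_rev[ri] = false;
    out_cigar[ri] = NA_STRING;
    if (m < k) continue;
    const double thr = 20.0 + 8.0 * std::log(static_cast<double>(m));
    votes.clear();
    // seed collection
    {
      uint64_t kmer = 0; int run = 0;
      for (int i = 0; i < m; ++i) {
        int c = base2code(read[i]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | static_cast<uint64_t>(c)) & mask;
        ++run;
        int qpos = i - k + 1;
        if (run >= k && (qpos % seed_step) == 0) {
          auto it = idx->map.find(kmer);
          if (it == idx->map.end()) continue;
          if (static_cast<int>(it->second.size()) > 128) continue;  // repeat k-mer
          for (uint64_t h : it->second) {
            int ref = static_cast<int>(h >> 32);
            int pos = static_cast<int>((h & 0xFFFFFFFFULL) >> 1);
            int strand = static_cast<int>(h & 1ULL);
            long diag;
            if (strand == 0) diag = static_cast<long>(pos) - qpos;
            else             diag = static_cast<long>(pos) - (m - k - qpos);
            uint64_t key = (static_cast<uint64_t>(strand) << 63) |
                           (static_cast<uint64_t>(ref) << 40) |
                           (static_cast<uint64_t>(diag + 2000000) & 0xFFFFFFFFFFULL);
            votes[key]++;
          }
        }
      }
    }
    if (votes.empty()) continue;
    // candidate selection: sort by votes, merge nearby diagonals
    std::vector<std::pair<uint64_t, int>> cand(votes.begin(), votes.end());
    std::sort(cand.begin(), cand.end(), [](const std::pair<uint64_t,int>& a,
                                           const std::pair<uint64_t,int>& b) {
      if (a.second != b.second) return a.second > b.second;
      return a.first < b.first;
    });
    struct Cand { int strand, ref; long diag; };
    std::vector<Cand> chosen;
    for (auto& cv : cand) {
      int strand = static_cast<int>(cv.first >> 63);
      int ref = static_cast<int>((cv.first >> 40) & 0x7FFFFF);
      long diag = static_cast<long>(cv.first & 0xFFFFFFFFFFULL) - 2000000;
      bool near = false;
      for (auto& c : chosen)
        if (c.strand == strand && c.ref == ref && std::labs(c.diag - diag) <= band)
          { near = true; break; }
      if (near) continue;
      chosen.push_back({strand, ref, diag});
      if (static_cast<int>(chosen.size()) >= max_candidates) break;
    }
    // evaluate candidates
    std::string rc;  // lazily computed
    int best = -1, second = 0, nbest = 0;
    AlnResult bestres; Cand bestc{0, 0, 0}; int best_ws = 0;
    for (auto& c : chosen) {
      const std::string& rseq = idx->seqs[c.ref];
      const int RL = static_cast<int>(rseq.size());
      long ws = c.diag - band, we = c.diag + m + band;
      if (ws < 0) ws = 0;
      if (we > RL) we = RL;
      if (we - ws < k) continue;
      const std::string* qp = &read;
      if (c.strand == 1) { if (rc.empty()) rc = revcomp_str(read); qp = &rc; }
      AlnResult r = align_window(*qp, rseq.c_str() + ws,
                                 static_cast<int>(we - ws), mode_local,
                                 match, mismatch, gap_open, gap_ext);
      if (r.score > best) {
        if (best > 0) second = best;
        best = r.score; nbest = 1; bestres = r; bestc = c;
        best_ws = static_cast<int>(ws);
      } else if (r.score == best) {
        ++nbest; second = best;
      } else if (r.score > second) {
        second = r.score;
      }
    }
    if (best < 0 || static_cast<double>(best) < thr) continue;
    // assemble cigar with clips
    std::string cig;
    if (bestres.qstart > 0) cig += std::to_string(bestres.qstart) + "S";
    cig += bestres.cigar;
    int tail = m - bestres.qend;
    if (tail > 0) cig += std::to_string(tail) + "S";
    int mapq = (nbest > 1) ? 0 : std::min(60, 6 * (best - second));
    out_unmapped[ri] = false;
    out_ref[ri] = bestc.ref + 1;
    out_pos[ri] = best_ws + bestres.rstart;
    out_rev[ri] = (bestc.strand == 1);
    out_cigar[ri] = cig;
    out_mapq[ri] = mapq;
    out_score[ri] = best;
  }
  return DataFrame::create(_["ref"] = out_ref, _["pos"] = out_pos,
                           _["rev"] = out_rev, _["cigar"] = out_cigar,
                           _["mapq"] = out_mapq, _["score"] = out_score,
                           _["unmapped"] = out_unmapped,
                           _["stringsAsFactors"] = false);
}

// ------------------------------------------------------------ cigar helpers

static void parse_cigar(const std::string& cig, std::vector<std::pair<int,char>>& ops) {
  ops.clear();
  int num = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') num = num * 10 + (c - '0');
    else { ops.push_back({num, c}); num = 0; }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_cigar_ref_len(CharacterVector cigars) {
  IntegerVector out(cigars.size());
  std::vector<std::pair<int,char>> ops;
  for (R_xlen_t i = 0; i < cigars.size(); ++i) {
    if (cigars[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    parse_cigar(as<std::string>(cigars[i]), ops);
    int L = 0;
    for (auto& o : ops) if (o.second == 'M' || o.second == 'D') L += o.first;
    out[i] = L;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_cigar_read_len(CharacterVector cigars) {
  IntegerVector out(cigars.size());
  std::vector<std::pair<int,char>> ops;
  for (R_xlen_t i = 0; i < cigars.size(); ++i) {
    if (cigars[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    parse_cigar(as<std::string>(cigars[i]), ops);
    int L = 0;
    for (auto& o : ops) if (o.second == 'M' || o.second == 'I' || o.second == 'S') L += o.first;
    out[i] = L;
  }
  return out;
}

// ------------------------------------------------------------ de Bruijn graph
// 128-bit packed k-mers so that assembly k may reach 63 (the full-scale
// k list of 41..81 is capped at 63 by this representation).

typedef unsigned __int128 kmer_t;

struct KmerHash {
  size_t operator()(const kmer_t& v) const {
    uint64_t lo = static_cast<uint64_t>(v);
    uint64_t hi = static_cast<uint64_t>(v >> 64);
    return std::hash<uint64_t>()(lo * 1000003ULL ^ hi);
  }
};

static inline kmer_t rc_kmer128(kmer_t v, int k) {
  kmer_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (kmer_t)(3ULL - (uint64_t)(v & 3));
    v >>= 2;
  }
  return r;
}

static std::string kmer128_to_str(kmer_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = CODE2BASE[(uint64_t)(v & 3)]; v >>= 2; }
  return s;
}

static inline uint64_t fold128(kmer_t v) {
  return static_cast<uint64_t>(v) ^ static_cast<uint64_t>(v >> 64);
}

struct DBG {
  int k;
  std::unordered_map<kmer_t, int, KmerHash> edges;  // canonical k-mer -> mult
  kmer_t mask_k, mask_n;                            // k-mer / (k-1)-mer masks
};

static inline kmer_t canon(kmer_t v, int k) {
  kmer_t r = rc_kmer128(v, k);
  return v < r ? v : r;
}

static inline bool has_edge(const DBG& g, kmer_t kmer) {
  return g.edges.count(canon(kmer, g.k)) > 0;
}

// oriented node = (k-1)-mer; out-edges append one base
static inline int out_degree(const DBG& g, kmer_t node, kmer_t* out_kmer) {
  int d = 0;
  for (uint64_t b = 0; b < 4; ++b) {
    kmer_t km = ((node << 2) | (kmer_t)b) & g.mask_k;
    if (has_edge(g, km)) { if (d == 0 && out_kmer) *out_kmer = km; ++d; }
  }
  return d;
}
static inline int in_degree(const DBG& g, kmer_t node, kmer_t* in_kmer) {
  int d = 0;
  for (uint64_t b = 0; b < 4; ++b) {
    kmer_t km = ((kmer_t)b << (2 * (g.k - 1))) | node;
    if (has_edge(g, km)) { if (d == 0 && in_kmer) *in_kmer = km; ++d; }
  }
  return d;
}

struct Unitig {
  std::string seq;
  double mean_mult;
  kmer_t left_node, right_node;
  std::vector<kmer_t> kmers;  // canonical
  int n_edges;
};

static void build_unitigs(const DBG& g, std::vector<Unitig>& out) {
  out.clear();
  std::vector<kmer_t> keys;
  keys.reserve(g.edges.size());
  for (auto& kv : g.edges) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  std::unordered_set<kmer_t, KmerHash> used;
  const int k = g.k;
  for (kmer_t start : keys) {
    if (used.count(start)) continue;
    // oriented edge = the canonical k-mer itself
    std::vector<kmer_t> path; path.push_back(start);
    used.insert(start);
    kmer_t cur = start;
    // extend right
    while (true) {
      kmer_t suf = cur & g.mask_n;
      kmer_t nxt;
      if (out_degree(g, suf, &nxt) != 1) break;
      if (in_degree(g, suf, nullptr) != 1) break;
      kmer_t cn = canon(nxt, k);
      if (used.count(cn)) break;
      path.push_back(nxt); used.insert(cn); cur = nxt;
    }
    // extend left
    std::vector<kmer_t> lpath;
    cur = start;
    while (true) {
      kmer_t pre = cur >> 2;
      kmer_t prv;
      if (in_degree(g, pre, &prv) != 1) break;
      if (out_degree(g, pre, nullptr) != 1) break;
      kmer_t cn = canon(prv, k);
      if (used.count(cn)) break;
      lpath.push_back(prv); used.insert(cn); cur = prv;
    }
    std::reverse(lpath.begin(), lpath.end());
    lpath.insert(lpath.end(), path.begin(), path.end());
    // sequence from oriented k-mer path
    Unitig u;
    u.seq = kmer128_to_str(lpath[0], k);
    double msum = g.edges.at(canon(lpath[0], k));
    u.kmers.push_back(canon(lpath[0], k));
    for (size_t i = 1; i < lpath.size(); ++i) {
      u.seq.push_back(CODE2BASE[(uint64_t)(lpath[i] & 3)]);
      kmer_t cn = canon(lpath[i], k);
      msum += g.edges.at(cn);
      u.kmers.push_back(cn);
    }
    u.mean_mult = msum / static_cast<double>(lpath.size());
    u.left_node = lpath.front() >> 2;
    u.right_node = lpath.back() & g.mask_n;
    u.n_edges = static_cast<int>(lpath.size());
    out.push_back(std::move(u));
  }
}

// [[Rcpp::export]]
CharacterVector cpp_assemble(CharacterVector reads, int k, int min_mult,
                             int tip_len, bool pop_bubbles = true) {
  if (k < 5 || k > 63) stop("assembly k must be between 5 and 63");
  DBG g;
  g.k = k;
  g.mask_k = ((kmer_t)1 << (2 * k)) - 1;
  g.mask_n = ((kmer_t)1 << (2 * (k - 1))) - 1;
  // count canonical k-mers
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    const int L = static_cast<int>(s.size());
    kmer_t kmer = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = base2code(s[i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (kmer_t)c) & g.mask_k;
      if (++run >= k) g.edges[canon(kmer, k)]++;
    }
  }
  // drop weak edges
  for (auto it = g.edges.begin(); it != g.edges.end();) {
    if (it->second < min_mult) it = g.edges.erase(it);
    else ++it;
  }
  // iterative tip clipping and bubble popping
  std::vector<Unitig> uts;
  for (int iter = 0; iter < 16; ++iter) {
    build_unitigs(g, uts);
    std::unordered_set<kmer_t, KmerHash> drop;
    // tips: exactly one dangling end, shorter than tip_len
    for (auto& u : uts) {
      bool dl = in_degree(g, u.left_node, nullptr) == 0;
      bool dr = out_degree(g, u.right_node, nullptr) == 0;
      if ((dl != dr) && static_cast<int>(u.seq.size()) < tip_len) {
        for (kmer_t km : u.kmers) drop.insert(km);
      }
    }
    // simple bubbles: two unitigs sharing both endpoint nodes
    if (pop_bubbles) {
      std::unordered_map<uint64_t, std::vector<int>> ends;
      for (size_t i = 0; i < uts.size(); ++i) {
        uint64_t a = fold128(uts[i].left_node), b = fold128(uts[i].right_node);
        uint64_t ra = fold128(rc_kmer128(uts[i].right_node, k - 1));
        uint64_t rb = fold128(rc_kmer128(uts[i].left_node, k - 1));
        uint64_t key1 = a * 1000003ULL ^ b;
        uint64_t key2 = ra * 1000003ULL ^ rb;
        ends[std::min(key1, key2)].push_back(static_cast<int>(i));
      }
      for (auto& kv : ends) {
        if (kv.second.size() < 2) continue;
        // keep highest mean multiplicity (ties: lexicographically smaller seq)
        int keep = kv.second[0];
        for (int i : kv.second) {
          if (uts[i].mean_mult > uts[keep].mean_mult ||
              (uts[i].mean_mult == uts[keep].mean_mult &&
               uts[i].seq < uts[keep].seq)) keep = i;
        }
        for (int i : kv.second) {
          if (i == keep) continue;
          // only pop arms of similar length (heterozygosity-scale bubbles)
          double lr = static_cast<double>(uts[i].seq.size()) /
                      static_cast<double>(uts[keep].seq.size());
          if (lr < 0.8 || lr > 1.25) continue;
          for (kmer_t km : uts[i].kmers) drop.insert(km);
        }
      }
    }
    if (drop.empty()) break;
    for (kmer_t km : drop) g.edges.erase(km);
  }
  build_unitigs(g, uts);
  std::vector<std::string> contigs;
  for (auto& u : uts) {
    std::string rc = revcomp_str(u.seq);
    contigs.push_back(u.seq < rc ? u.seq : rc);
  }
  std::sort(contigs.begin(), contigs.end());
  contigs.erase(std::unique(contigs.begin(), contigs.end()), contigs.end());
  return wrap(contigs);
}

// ----------------------------------------------------- exact anchor segments

// Maximal exact-match runs of query k-mers against the index, both strands.
// For strand 0 (forward): ref[rstart, rend) == query[qstart, qend).
// For strand 1 (reverse): ref[rstart, rend) == revcomp(query[qstart, qend)).
// [[Rcpp::export]]
DataFrame cpp_exact_segments(SEXP ptr, std::string query, int max_hits = 64) {
  XPtr<KmerIndex> idx(ptr);
  const int k = idx->k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  const int m = static_cast<int>(query.size());
  // hit tuples packed for sorting: strand, ref, diag, qpos
  struct Hit { int strand, ref; long diag; int qpos; };
  std::vector<Hit> hits;
  uint64_t kmer = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = base2code(query[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | static_cast<uint64_t>(c)) & mask;
    if (++run < k) continue;
    int qpos = i - k + 1;
    auto it = idx->map.find(kmer);
    if (it == idx->map.end()) continue;
    if (static_cast<int>(it->second.size()) > max_hits) continue;
    for (uint64_t h : it->second) {
      int ref = static_cast<int>(h >> 32);
      int pos = static_cast<int>((h & 0xFFFFFFFFULL) >> 1);
      int strand = static_cast<int>(h & 1ULL);
      long diag = (strand == 0) ? static_cast<long>(pos) - qpos
                                : static_cast<long>(pos) + qpos;
      hits.push_back({strand, ref, diag, qpos});
    }
  }
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.strand != b.strand) return a.strand < b.strand;
    if (a.ref != b.ref) return a.ref < b.ref;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qpos < b.qpos;
  });
  std::vector<int> ref, strand, qs, qe, rs, re;
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i;
    while (j + 1 < hits.size() && hits[j + 1].strand == hits[i].strand &&
           hits[j + 1].ref == hits[i].ref && hits[j + 1].diag == hits[i].diag &&
           hits[j + 1].qpos == hits[j].qpos + 1) ++j;
    int q0 = hits[i].qpos, q1 = hits[j].qpos;
    ref.push_back(hits[i].ref + 1);
    strand.push_back(hits[i].strand);
    qs.push_back(q0); qe.push_back(q1 + k);
    if (hits[i].strand == 0) {
      rs.push_back(static_cast<int>(hits[i].diag + q0));
      re.push_back(static_cast<int>(hits[i].diag + q1 + k));
    } else {
      rs.push_back(static_cast<int>(hits[i].diag - q1));
      re.push_back(static_cast<int>(hits[i].diag - q0 + k));
    }
    i = j + 1;
  }
  return DataFrame::create(_["ref"] = ref, _["rev"] = strand, _["qstart"] = qs,
                           _["qend"] = qe, _["rstart"] = rs, _["rend"] = re,
                           _["stringsAsFactors"] = false);
}

// Best co-linear chain over exact segments (single ref/strand group).
// Inputs must be transformed so that a chain has both q and r increasing
// (the R layer mirrors reverse-strand r coordinates). Returns 1-based indices
// of chained segments (in q order) and the chain score (matched bases).
// [[Rcpp::export]]
List cpp_chain_segments(IntegerVector qs, IntegerVector qe, IntegerVector rs,
                        IntegerVector re, int max_gap, int max_drift,
                        int slack = 15) {
  const int n = qs.size();
  if (n == 0) return List::create(_["idx"] = IntegerVector(0), _["score"] = 0);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (qs[a] != qs[b]) return qs[a] < qs[b];
    return rs[a] < rs[b];
  });
  int maxlen = 0;
  for (int i = 0; i < n; ++i) maxlen = std::max(maxlen, qe[i] - qs[i]);
  std::vector<double> best(n);
  std::vector<int> prev(n, -1);
  double gbest = -1; int gbi = -1;
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    int len = qe[i] - qs[i];
    best[i] = len;
    for (int jj = ii - 1; jj >= 0; --jj) {
      int j = ord[jj];
      if (qs[i] - qs[j] > max_gap + maxlen) break;
      int dq = qs[i] - qe[j];
      if (dq > max_gap || dq < -slack) continue;
      int dr = rs[i] - re[j];
      if (dr > max_gap + max_drift || dr < -slack) continue;
      if (std::abs(dq - dr) > max_drift) continue;
      double add = len - std::max(0, -dq);
      if (best[j] + add > best[i]) { best[i] = best[j] + add; prev[i] = j; }
    }
    if (best[i] > gbest) { gbest = best[i]; gbi = i; }
  }
  std::vector<int> chain;
  for (int c = gbi; c >= 0; c = prev[c]) chain.push_back(c + 1);
  std::reverse(chain.begin(), chain.end());
  return List::create(_["idx"] = wrap(chain), _["score"] = gbest);
}

// ---------------------------------------------------------------- pileup

// Accumulate base/deletion counts and insertion evidence over target sequences
// from alignments. seqs must already be in alignment orientation.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector target_len, IntegerVector tgt, IntegerVector pos,
                CharacterVector cigars, CharacterVector seqs) {
  const int nt = target_len.size();
  std::vector<IntegerMatrix> mats;
  for (int t = 0; t < nt; ++t) mats.push_back(IntegerMatrix(5, target_len[t]));
  // insertion evidence: map (target, pos, string) -> count
  std::map<std::tuple<int,int,std::string>, int> ins;
  std::vector<std::pair<int,char>> ops;
  for (R_xlen_t a = 0; a < pos.size(); ++a) {
    if (cigars[a] == NA_STRING) continue;
    int t = tgt[a] - 1;
    if (t < 0 || t >= nt) continue;
    parse_cigar(as<std::string>(cigars[a]), ops);
    std::string s = as<std::string>(seqs[a]);
    int rp = pos[a], qp = 0;
    IntegerMatrix& M = mats[t];
    const int L = target_len[t];
    for (auto& o : ops) {
      if (o.second == 'M') {
        for (int x = 0; x < o.first; ++x) {
          if (rp >= 0 && rp < L) {
            int c = base2code(s[qp]);
            if (c >= 0) M(c, rp) += 1;
          }
          ++rp; ++qp;
        }
      } else if (o.second == 'D') {
        for (int x = 0; x < o.first; ++x) {
          if (rp >= 0 && rp < L) M(4, rp) += 1;
          ++rp;
        }
      } else if (o.second == 'I') {
        if (rp > 0 && rp <= L)
          ins[std::make_tuple(t, rp, s.substr(qp, o.first))] += 1;
        qp += o.first;
      } else if (o.second == 'S') {
        qp += o.first;
      }
    }
  }
  std::vector<int> it_, ip_; std::vector<std::string> is_; std::vector<int> ic_;
  for (auto& kv : ins) {
    it_.push_back(std::get<0>(kv.first) + 1);
    ip_.push_back(std::get<1>(kv.first));
    is_.push_back(std::get<2>(kv.first));
    ic_.push_back(kv.second);
  }
  List matl(nt);
  for (int t = 0; t < nt; ++t) matl[t] = mats[t];
  return List::create(_["counts"] = matl,
                      _["ins"] = DataFrame::create(
                          _["target"] = wrap(it_), _["pos"] = wrap(ip_),
                          _["seq"] = wrap(is_), _["count"] = wrap(ic_),
                          _["stringsAsFactors"] = false));
}

// --------------------------------------------------- gap closing path search

struct PathSearch {
  const std::unordered_set<uint64_t>* kmers;
  int k;
  uint64_t mask_k, mask_n;
  uint64_t target;
  int max_len;
  long expansions, limit;
  int n_found;
  std::string found;
};

static void dfs_path(PathSearch& ps, uint64_t node, std::string& cur) {
  if (ps.n_found > 1 || ps.expansions > ps.limit) return;
  if (static_cast<int>(cur.size()) > ps.max_len) return;
  for (uint64_t b = 0; b < 4; ++b) {
    uint64_t km = ((node << 2) | b) & ps.mask_k;
    if (!ps.kmers->count(km)) continue;
    ++ps.expansions;
    cur.push_back(CODE2BASE[b]);
    if (km == ps.target) {
      ++ps.n_found;
      if (ps.n_found == 1) ps.found = cur;
      else if (ps.found != cur) { cur.pop_back(); return; }
      else --ps.n_found;  // same path revisited is impossible; keep safe
    } else {
      dfs_path(ps, km & ps.mask_n, cur);
    }
    cur.pop_back();
    if (ps.n_found > 1 || ps.expansions > ps.limit) return;
  }
}

// Search for a unique k-mer path from left anchor to right anchor in the
// directed graph of read k-mers (both strands). Returns the bridging sequence
// including both anchors, or "" if absent/ambiguous.
// [[Rcpp::export]]
std::string cpp_unique_path(CharacterVector reads, int k, std::string left,
                            std::string right, int max_len) {
  if (static_cast<int>(left.size()) != k || static_cast<int>(right.size()) != k)
    return "";
  std::unordered_set<uint64_t> kmers;
  uint64_t mask_k = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    for (int pass = 0; pass < 2; ++pass) {
      std::string s = as<std::string>(reads[r]);
      if (pass == 1) s = revcomp_str(s);
      uint64_t kmer = 0; int run = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c = base2code(s[i]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | static_cast<uint64_t>(c)) & mask_k;
        if (++run >= k) kmers.insert(kmer);
      }
    }
  }
  uint64_t lv = 0, rv = 0;
  for (char c : left)  { int b = base2code(c); if (b < 0) return ""; lv = ((lv << 2) | b) & mask_k; }
  for (char c : right) { int b = base2code(c); if (b < 0) return ""; rv = ((rv << 2) | b) & mask_k; }
  if (!kmers.count(lv) || !kmers.count(rv)) return "";
  PathSearch ps;
  ps.kmers = &kmers; ps.k = k; ps.mask_k = mask_k;
  ps.mask_n = (1ULL << (2 * (k - 1))) - 1ULL;
  ps.target = rv; ps.max_len = max_len;
  ps.expansions = 0; ps.limit = 200000; ps.n_found = 0;
  std::string cur;
  dfs_path(ps, lv & ps.mask_n, cur);
  if (ps.n_found != 1 || ps.expansions > ps.limit) return "";
  return left + ps.found;
}

// ------------------------------------------------------- banded identity

// Banded longest-common-subsequence match count between two sequences;
// used to score identity of an aligned segment pair (small indel drift).
// [[Rcpp::export]]
int cpp_banded_matches(std::string a, std::string b, int band) {
  const int la = static_cast<int>(a.size()), lb = static_cast<int>(b.size());
  if (la == 0 || lb == 0) return 0;
  const int W = 2 * band + 1;
  std::vector<int> prevr(W, 0), curr(W, 0);
  // cell (i, d): j = center(i) + d - band, center(i) = round(i * lb / la)
  auto centre = [&](int i) { return static_cast<int>(
      static_cast<long long>(i) * lb / la); };
  for (int i = 1; i <= la; ++i) {
    int ci = centre(i), cp = centre(i - 1);
    int shift = ci - cp;
    for (int d = 0; d < W; ++d) {
      int j = ci + d - band;
      if (j < 0 || j > lb) { curr[d] = -1000000; continue; }
      int bestv = 0;
      if (j == 0) { curr[d] = 0; continue; }
      // up: (i-1, j) -> d_up = j - cp + band = d + shift
      int du = d + shift;
      if (du >= 0 && du < W && prevr[du] > bestv) bestv = prevr[du];
      // left: (i, j-1)
      if (d - 1 >= 0 && curr[d - 1] > bestv) bestv = curr[d - 1];
      // diag: (i-1, j-1) -> d_diag = d + shift - 1
      int dd = d + shift - 1;
      if (dd >= 0 && dd < W && prevr[dd] >= 0) {
        int v = prevr[dd] + ((a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? 1 : 0);
        if (v > bestv) bestv = v;
      }
      curr[d] = bestv;
    }
    std::swap(prevr, curr);
  }
  int best = 0;
  for (int d = 0; d < W; ++d) best = std::max(best, prevr[d]);
  return best;
}

// ------------------------------------------------------------- quality trim

// Leading/trailing quality trim followed by sliding-window clip.
// Returns per-read [start, end) of the retained interval (0-based half-open);
// end <= start means the read is fully trimmed.
// [[Rcpp::export]]
IntegerMatrix cpp_trim_bounds(CharacterVector quals, int lead_trail_q,
                              int window_len, double window_q) {
  const R_xlen_t n = quals.size();
  IntegerMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    const int L = static_cast<int>(q.size());
    int s = 0, e = L;
    while (s < e && (q[s] - 33) < lead_trail_q) ++s;
    while (e > s && (q[e - 1] - 33) < lead_trail_q) --e;
    if (e - s >= window_len && window_len > 0) {
      int wsum = 0;
      for (int j = s; j < s + window_len; ++j) wsum += q[j] - 33;
      int w0 = s;
      while (true) {
        if (static_cast<double>(wsum) / window_len < window_q) { e = w0; break; }
        if (w0 + window_len >= e) break;
        wsum += (q[w0 + window_len] - 33) - (q[w0] - 33);
        ++w0;
      }
    }
    out(i, 0) = s; out(i, 1) = e;
  }
  return out;
}
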