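// Low-level sequence kernels: canonical k-mer counting, De Bruijn unitig
// assembly, seed-and-extend read placement, suffix/prefix overlap search and
// inverted-repeat detection. K-mers up to 63 bases are 2-bit packed into
// 128-bit words; larger K (the published assembly sweep runs to 99) falls
// back to string-keyed containers with identical semantics. The canonical
// representative of a k-mer follows the middle-base rule: of a window and
// its reverse complement, exactly one has A or C at the centre position
// (odd k), and that one is counted.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

typedef unsigned __int128 u128;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

struct U128Hash {
  size_t operator()(const u128 &x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^ (hi + 0x9E3779B97F4A7C15ULL + (lo << 6) + (lo >> 2));
    h ^= h >> 31; h *= 0xBF58476D1CE4E5B9ULL; h ^= h >> 27;
    return (size_t)h;
  }
};

typedef std::unordered_map<u128, uint32_t, U128Hash> KmerMap;
typedef std::unordered_set<u128, U128Hash> KmerSet;
typedef std::unordered_map<std::string, uint32_t> StrMap;
typedef std::unordered_set<std::string> StrSet;

static inline u128 mask_for(int k) {
  if (k >= 64) return ~(u128)0;
  return ((u128)1 << (2 * k)) - 1;
}

static inline u128 revcomp_code(u128 x, int k) {
  u128 r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (unsigned)(x & 3));
    x >>= 2;
  }
  return r;
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    default: break; // N stays N
    }
  }
  return r;
}

// middle base of an odd-k code; leftmost base sits in the highest 2 bits
static inline int middle_base(u128 x, int k) {
  return (int)((x >> (2 * (k / 2))) & 3);
}

static inline u128 canon_code(u128 x, int k) {
  return middle_base(x, k) <= 1 ? x : revcomp_code(x, k);
}

static inline std::string canon_str(const std::string &x) {
  char mid = x[x.size() / 2];
  return (mid == 'A' || mid == 'C') ? x : revcomp_str(x);
}

static std::string decode_kmer(u128 x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[(int)(x & 3)];
    x >>= 2;
  }
  return s;
}

static bool encode_window(const char *s, int k, u128 &out) {
  u128 x = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    x = (x << 2) | (unsigned)c;
  }
  out = x;
  return true;
}

// Count canonical k-mers of every length-k window (bit-packed, k <= 63).
static void count_into(KmerMap &counts, const std::string &seq, int k) {
  const int L = (int)seq.size();
  if (L < k) return;
  u128 fwd = 0, rc = 0;
  const u128 msk = mask_for(k);
  const int rc_shift = 2 * (k - 1);
  int valid = 0;
  for (int i = 0; i < L; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (unsigned)c) & msk;
    rc = (rc >> 2) | ((u128)(3 - c) << rc_shift);
    if (valid < k) ++valid;
    if (valid == k) {
      int mid = base_code(seq[i - k / 2]);
      ++counts[(mid <= 1) ? fwd : rc];
    }
  }
}

// string-keyed variant for k > 63
static void count_into_str(StrMap &counts, const std::string &seq, int k) {
  const int L = (int)seq.size();
  if (L < k) return;
  int valid = 0;
  for (int i = 0; i < L; ++i) {
    if (base_code(seq[i]) < 0) { valid = 0; continue; }
    if (valid < k) ++valid;
    if (valid == k) ++counts[canon_str(seq.substr(i - k + 1, k))];
  }
}

static long long total_windows(const std::string &seq, int k) {
  return std::max<long long>(0, (long long)seq.size() - k + 1);
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  long long tot = 0, counted = 0;
  CharacterVector kmers;
  IntegerVector cnt;
  if (k <= 63) {
    KmerMap counts;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
      std::string s = as<std::string>(seqs[i]);
      tot += total_windows(s, k);
      count_into(counts, s, k);
    }
    std::vector<std::pair<u128, uint32_t>> v(counts.begin(), counts.end());
    std::sort(v.begin(), v.end(),
              [](const std::pair<u128, uint32_t> &a,
                 const std::pair<u128, uint32_t> &b) {
                return a.first < b.first;
              });
    kmers = CharacterVector(v.size());
    cnt = IntegerVector(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
      kmers[i] = decode_kmer(v[i].first, k);
      cnt[i] = (int)v[i].second;
      counted += v[i].second;
    }
  } else {
    StrMap counts;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
      std::string s = as<std::string>(seqs[i]);
      tot += total_windows(s, k);
      count_into_str(counts, s, k);
    }
    std::vector<std::pair<std::string, uint32_t>> v(counts.begin(),
                                                    counts.end());
    std::sort(v.begin(), v.end());
    kmers = CharacterVector(v.size());
    cnt = IntegerVector(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
      kmers[i] = v[i].first;
      cnt[i] = (int)v[i].second;
      counted += v[i].second;
    }
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt,
                      _["skipped"] = (double)(tot - counted));
}

static KmerSet build_set(CharacterVector kmers, int k) {
  KmerSet set;
  set.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    u128 x;
    const char *p = CHAR(STRING_ELT(kmers, i));
    if (encode_window(p, k, x)) set.insert(canon_code(x, k));
  }
  return set;
}

static StrSet build_set_str(CharacterVector kmers) {
  StrSet set;
  set.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    set.insert(canon_str(as<std::string>(kmers[i])));
  return set;
}

// per-sequence window scan shared by matching and containment: calls
// hit(bool) for every valid window
template <class F>
static void scan_windows(const char *s, int L, int k, const KmerSet *bits,
                         const StrSet *strs, F &&hit) {
  if (bits) {
    const u128 msk = mask_for(k);
    const int rc_shift = 2 * (k - 1);
    u128 fwd = 0, rc = 0;
    int valid = 0;
    for (int j = 0; j < L; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { valid = 0; continue; }
      fwd = ((fwd << 2) | (unsigned)c) & msk;
      rc = (rc >> 2) | ((u128)(3 - c) << rc_shift);
      if (valid < k) ++valid;
      if (valid == k) {
        int mid = base_code(s[j - k / 2]);
        if (!hit(bits->count(mid <= 1 ? fwd : rc) > 0)) return;
      }
    }
  } else {
    std::string str(s, L);
    int valid = 0;
    for (int j = 0; j < L; ++j) {
      if (base_code(s[j]) < 0) { valid = 0; continue; }
      if (valid < k) ++valid;
      if (valid == k) {
        if (!hit(strs->count(canon_str(str.substr(j - k + 1, k))) > 0))
          return;
      }
    }
  }
}

// TRUE for each sequence containing at least one canonical k-mer in `kmers`
// [[Rcpp::export]]
LogicalVector cpp_seqs_match(CharacterVector seqs, int k,
                             CharacterVector kmers) {
  KmerSet bits;
  StrSet strs;
  bool packed = k <= 63;
  if (packed) bits = build_set(kmers, k);
  else strs = build_set_str(kmers);
  LogicalVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = (int)LENGTH(STRING_ELT(seqs, i));
    bool found = false;
    scan_windows(s, L, k, packed ? &bits : nullptr,
                 packed ? nullptr : &strs, [&](bool in) {
                   if (in) { found = true; return false; }
                   return true;
                 });
    out[i] = found;
  }
  return out;
}

// fraction of a sequence's canonical k-mer windows present in `kmers`
// [[Rcpp::export]]
NumericVector cpp_seq_containment(CharacterVector seqs, int k,
                                  CharacterVector kmers) {
  KmerSet bits;
  StrSet strs;
  bool packed = k <= 63;
  if (packed) bits = build_set(kmers, k);
  else strs = build_set_str(kmers);
  NumericVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = (int)LENGTH(STRING_ELT(seqs, i));
    long long n = 0, in = 0;
    scan_windows(s, L, k, packed ? &bits : nullptr,
                 packed ? nullptr : &strs, [&](bool hit) {
                   ++n;
                   if (hit) ++in;
                   return true;
                 });
    out[i] = n == 0 ? 0.0 : (double)in / (double)n;
  }
  return out;
}

// ---------------------------------------------------------------------------
// De Bruijn unitig assembler
// ---------------------------------------------------------------------------

// node-centric graph over canonical K-mers, 2-bit packed (K <= 63)
struct BitGraph {
  typedef u128 key;
  typedef KmerSet set_type;
  KmerMap counts;
  int K;
  u128 msk;
  BitGraph(int K_) : K(K_), msk(mask_for(K_)) {}
  void add_seq(const std::string &s) { count_into(counts, s, K); }
  size_t size() const { return counts.size(); }
  void drop_below(int min_cov) {
    for (auto it = counts.begin(); it != counts.end();)
      if ((int)it->second < min_cov) it = counts.erase(it); else ++it;
  }
  void erase(const key &x) { counts.erase(x); }
  key canon(const key &x) const { return canon_code(x, K); }
  key rc(const key &x) const { return revcomp_code(x, K); }
  bool has(const key &x) const { return counts.count(canon(x)) > 0; }
  double cov(const key &x) const {
    auto it = counts.find(canon(x));
    return it == counts.end() ? 0.0 : (double)it->second;
  }
  int succs(const key &x, key out[4]) const {
    int n = 0;
    for (unsigned b = 0; b < 4; ++b) {
      key y = ((x << 2) | b) & msk;
      if (has(y)) out[n++] = y;
    }
    return n;
  }
  int preds(const key &x, key out[4]) const {
    int n = 0;
    for (unsigned b = 0; b < 4; ++b) {
      key y = (x >> 2) | ((u128)b << (2 * (K - 1)));
      if (has(y)) out[n++] = y;
    }
    return n;
  }
  std::vector<key> sorted_keys() const {
    std::vector<key> keys;
    keys.reserve(counts.size());
    for (auto &kv : counts) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    return keys;
  }
  std::string decode(const key &x) const { return decode_kmer(x, K); }
  char last_base(const key &x) const { return BASES[(int)(x & 3)]; }
};

// string-keyed fallback for K > 63; identical contract
struct StrGraph {
  typedef std::string key;
  typedef StrSet set_type;
  StrMap counts;
  int K;
  StrGraph(int K_) : K(K_) {}
  void add_seq(const std::string &s) { count_into_str(counts, s, K); }
  size_t size() const { return counts.size(); }
  void drop_below(int min_cov) {
    for (auto it = counts.begin(); it != counts.end();)
      if ((int)it->second < min_cov) it = counts.erase(it); else ++it;
  }
  void erase(const key &x) { counts.erase(x); }
  key canon(const key &x) const { return canon_str(x); }
  key rc(const key &x) const { return revcomp_str(x); }
  bool has(const key &x) const { return counts.count(canon(x)) > 0; }
  double cov(const key &x) const {
    auto it = counts.find(canon(x));
    return it == counts.end() ? 0.0 : (double)it->second;
  }
  int succs(const key &x, key out[4]) const {
    int n = 0;
    std::string y = x.substr(1) + "A";
    for (int b = 0; b < 4; ++b) {
      y[K - 1] = BASES[b];
      if (has(y)) out[n++] = y;
    }
    return n;
  }
  int preds(const key &x, key out[4]) const {
    int n = 0;
    std::string y = "A" + x.substr(0, K - 1);
    for (int b = 0; b < 4; ++b) {
      y[0] = BASES[b];
      if (has(y)) out[n++] = y;
    }
    return n;
  }
  std::vector<key> sorted_keys() const {
    std::vector<key> keys;
    keys.reserve(counts.size());
    for (auto &kv : counts) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    return keys;
  }
  std::string decode(const key &x) const { return x; }
  char last_base(const key &x) const { return x[K - 1]; }
};

// maximal unambiguous paths; leftover components are simple cycles
template <class G>
static std::vector<std::vector<typename G::key>> build_unitigs(const G &g) {
  typedef typename G::key key;
  std::vector<std::vector<key>> paths;
  typename G::set_type visited;
  visited.reserve(g.size() * 2);
  key nb[4], tmp[4];
  std::vector<key> keys = g.sorted_keys();
  for (const key &c : keys) {
    if (visited.count(c)) continue;
    for (int o = 0; o < 2; ++o) {
      if (visited.count(c)) break;
      key x = (o == 0) ? c : g.rc(c);
      int ind = g.preds(x, nb);
      bool start;
      if (ind != 1) start = true;
      else start = g.succs(nb[0], tmp) != 1;
      if (!start) continue;
      std::vector<key> path;
      path.push_back(x);
      visited.insert(g.canon(x));
      key cur = x;
      while (true) {
        int ns = g.succs(cur, nb);
        if (ns != 1) break;
        key nxt = nb[0];
        if (g.preds(nxt, tmp) != 1) break;
        if (visited.count(g.canon(nxt))) break;
        path.push_back(nxt);
        visited.insert(g.canon(nxt));
        cur = nxt;
      }
      paths.push_back(std::move(path));
    }
  }
  for (const key &c : keys) {
    if (visited.count(c)) continue;
    std::vector<key> path;
    key cur = c;
    while (!visited.count(g.canon(cur))) {
      path.push_back(cur);
      visited.insert(g.canon(cur));
      int ns = g.succs(cur, nb);
      if (ns < 1) break;
      cur = nb[0];
    }
    if (!path.empty()) paths.push_back(std::move(path));
  }
  return paths;
}

template <class G>
static List assemble_with(G &g, CharacterVector seqs, int K, int min_cov,
                          int tip_rounds) {
  typedef typename G::key key;
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    g.add_seq(as<std::string>(seqs[i]));
  g.drop_below(min_cov);
  key nb[4];
  for (int round = 0; round < tip_rounds; ++round) {
    auto paths = build_unitigs(g);
    std::vector<key> to_remove;
    for (auto &p : paths) {
      if ((int)p.size() >= K + 1) continue; // >= 2K bases
      bool in0 = g.preds(p.front(), nb) == 0;
      bool out0 = g.succs(p.back(), nb) == 0;
      if (in0 != out0) // a dead end hanging off a branch
        for (const key &x : p) to_remove.push_back(g.canon(x));
    }
    if (to_remove.empty()) break;
    for (const key &x : to_remove) g.erase(x);
  }
  auto paths = build_unitigs(g);
  std::vector<std::string> seqs_out;
  std::vector<double> cov_out;
  std::unordered_set<std::string> seen;
  for (auto &p : paths) {
    std::string s = g.decode(p[0]);
    s.reserve(p.size() + K - 1);
    for (size_t i = 1; i < p.size(); ++i) s.push_back(g.last_base(p[i]));
    std::string r = revcomp_str(s);
    const std::string &rep = (s <= r) ? s : r;
    if (seen.count(rep)) continue;
    seen.insert(rep);
    double c = 0;
    for (const key &x : p) c += g.cov(x);
    // a cycle path already carries a K-1 self-overlap (its last K-1 bases
    // equal its first K-1), which downstream overlap merging closes
    seqs_out.push_back(rep);
    cov_out.push_back(c / p.size());
  }
  return List::create(_["sequence"] = wrap(seqs_out),
                      _["coverage"] = wrap(cov_out));
}

// Assemble unitigs from reads: coverage cutoff, iterative tip clipping,
// then maximal unambiguous paths.
// [[Rcpp::export]]
List cpp_assemble(CharacterVector seqs, int K, int min_cov, int tip_rounds) {
  if (K <= 63) {
    BitGraph g(K);
    return assemble_with(g, seqs, K, min_cov, tip_rounds);
  }
  StrGraph g(K);
  return assemble_with(g, seqs, K, min_cov, tip_rounds);
}

// ---------------------------------------------------------------------------
// Seed-and-extend ungapped read placement
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        int seed_len, int max_seed_hits = 64) {
  if (seed_len > 63) stop("seed_len must be <= 63");
  // index: plain (strand-specific) seed codes -> (ref, pos)
  std::unordered_map<u128, std::vector<std::pair<int, int>>, U128Hash> idx;
  std::vector<std::string> refseq(refs.size());
  for (R_xlen_t r = 0; r < refs.size(); ++r) {
    refseq[r] = as<std::string>(refs[r]);
    const std::string &s = refseq[r];
    if ((int)s.size() < seed_len) continue;
    u128 x = 0;
    const u128 msk = mask_for(seed_len);
    int valid = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; continue; }
      x = ((x << 2) | (unsigned)c) & msk;
      if (valid < seed_len) ++valid;
      if (valid == seed_len) idx[x].push_back({(int)r, i - seed_len + 1});
    }
  }
  R_xlen_t n = reads.size();
  IntegerVector o_ref(n), o_pos(n), o_strand(n), o_match(n), o_mm(n),
      o_ohl(n), o_ohr(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = (int)rd.size();
    int best_score = -1;
    int b_ref = NA_INTEGER, b_pos = 0, b_strand = 0, b_mm = 0, b_ohl = 0,
        b_ohr = 0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? rd : revcomp_str(rd);
      if (L < seed_len) break;
      int offs[3] = {0, (L - seed_len) / 2, L - seed_len};
      std::unordered_set<long long> tried;
      for (int oi = 0; oi < 3; ++oi) {
        int off = offs[oi];
        u128 x;
        if (!encode_window(q.c_str() + off, seed_len, x)) continue;
        auto it = idx.find(x);
        if (it == idx.end() || (int)it->second.size() > max_seed_hits)
          continue;
        for (auto &hit : it->second) {
          int rref = hit.first, d = hit.second - off;
          long long kk = ((long long)rref << 40) ^
                         ((long long)(d + 1000000) << 1) ^ strand;
          if (tried.count(kk)) continue;
          tried.insert(kk);
          const std::string &R = refseq[rref];
          int RL = (int)R.size();
          int match = 0, mm = 0;
          for (int j = 0; j < L; ++j) {
            int p = d + j;
            if (p < 0 || p >= RL) continue;
            if (q[j] == R[p]) ++match; else ++mm;
          }
          int ohl = std::max(0, -d);
          int ohr = std::max(0, d + L - RL);
          if (match > best_score) {
            best_score = match;
            b_ref = rref + 1; b_pos = d; b_strand = strand == 0 ? 1 : -1;
            b_mm = mm; b_ohl = ohl; b_ohr = ohr;
          }
        }
      }
    }
    o_ref[i] = b_ref; o_pos[i] = b_pos; o_strand[i] = b_strand;
    o_match[i] = best_score < 0 ? NA_INTEGER : best_score;
    o_mm[i] = b_mm; o_ohl[i] = b_ohl; o_ohr[i] = b_ohr;
  }
  return DataFrame::create(_["ref"] = o_ref, _["pos"] = o_pos,
                           _["strand"] = o_strand, _["matches"] = o_match,
                           _["mismatches"] = o_mm,
                           _["overhang_left"] = o_ohl,
                           _["overhang_right"] = o_ohr);
}

// ---------------------------------------------------------------------------
// Overlap and inverted-repeat search
// ---------------------------------------------------------------------------

// Longest l >= min_overlap with suffix_l(a) matching prefix_l(b) at mismatch
// rate <= max_mm_rate (anchored on an exact probe of b's first bases).
// max_allowed caps the considered overlap length (< 0: min(|a|, |b|)); the
// cap excludes trivial full-length self matches when a == b.
// Returns -1 when none.
// [[Rcpp::export]]
int cpp_best_overlap(std::string a, std::string b, int min_overlap,
                     double max_mm_rate, int max_allowed = -1) {
  int la = (int)a.size(), lb = (int)b.size();
  int maxov = std::min(la, lb);
  if (max_allowed >= 0 && max_allowed < maxov) maxov = max_allowed;
  if (maxov < min_overlap) return -1;
  int probe_len = (max_mm_rate > 0) ? std::min(16, min_overlap) : min_overlap;
  std::string probe = b.substr(0, probe_len);
  int best = -1;
  size_t from = (size_t)(la - maxov);
  while (true) {
    size_t p = a.find(probe, from);
    if (p == std::string::npos) break;
    int l = la - (int)p;
    if (l >= min_overlap && l <= maxov) {
      int mm = 0;
      for (int j = probe_len; j < l; ++j)
        if (a[p + j] != b[j]) ++mm;
      if (mm <= (int)(max_mm_rate * l) && l > best) best = l;
    }
    from = p + 1;
  }
  return best;
}

// All maximal revcomp-palindromic interval pairs of length >= min_len:
// rows (start1, start2, len), 0-based, S[start1..start1+len) ==
// revcomp(S[start2..start2+len)). Seeded on shared seed_k-mers; seeds on
// one anti-diagonal share one maximal extension, tracked per diagonal.
// [[Rcpp::export]]
IntegerMatrix cpp_find_ir(std::string s, int min_len, int seed_k) {
  int L = (int)s.size();
  IntegerMatrix empty(0, 3);
  if (L < 2 * seed_k) return empty;
  std::string r = revcomp_str(s);
  std::unordered_map<u128, std::vector<int>, U128Hash> idx;
  const u128 msk = mask_for(seed_k);
  {
    u128 x = 0; int valid = 0;
    for (int i = 0; i < L; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; continue; }
      x = ((x << 2) | (unsigned)c) & msk;
      if (valid < seed_k) ++valid;
      if (valid == seed_k) idx[x].push_back(i - seed_k + 1);
    }
  }
  // match between s[i..] and r[j..]  <=>  s[i..i+l) == rc(s[m..m+l)),
  // m = L - j - l; i + m is invariant along a maximal extension
  std::unordered_map<long long, std::vector<std::pair<int, int>>> covered;
  std::vector<std::array<int, 3>> out;
  {
    u128 x = 0; int valid = 0;
    for (int j = 0; j < L; ++j) {
      int c = base_code(r[j]);
      if (c < 0) { valid = 0; continue; }
      x = ((x << 2) | (unsigned)c) & msk;
      if (valid < seed_k) ++valid;
      if (valid < seed_k) continue;
      auto it = idx.find(x);
      if (it == idx.end()) continue;
      int j0 = j - seed_k + 1;          // seed start in r
      int m = L - j0 - seed_k;          // start in s of the rc'd segment
      for (int i : it->second) {
        long long diag = (long long)i + m;
        bool done = false;
        auto cv = covered.find(diag);
        if (cv != covered.end())
          for (auto &iv : cv->second)
            if (i >= iv.first && i < iv.second) { done = true; break; }
        if (done) continue;
        // extend: s[ii..ii+l) == rc(s[mm..mm+l)); right: s[ii+l]==comp(s[mm-1]);
        // left: s[ii-1]==comp(s[mm+l])
        int ii = i, mm = m, l = seed_k;
        while (ii + l < L && mm - 1 >= 0) {
          int c1 = base_code(s[ii + l]), c2 = base_code(s[mm - 1]);
          if (c1 < 0 || c2 < 0 || c1 + c2 != 3) break;
          ++l; --mm;
        }
        while (ii - 1 >= 0 && mm + l < L) {
          int c1 = base_code(s[ii - 1]), c2 = base_code(s[mm + l]);
          if (c1 < 0 || c2 < 0 || c1 + c2 != 3) break;
          --ii; ++l;
        }
        covered[diag].push_back({ii, ii + l});
        if (l >= min_len) {
          int a1 = std::min(ii, mm), a2 = std::max(ii, mm);
          out.push_back({a1, a2, l});
        }
      }
    }
  }
  std::sort(out.begin(), out.end(),
            [](const std::array<int, 3> &a, const std::array<int, 3> &b) {
              if (a[2] != b[2]) return a[2] > b[2];
              if (a[0] != b[0]) return a[0] < b[0];
              return a[1] < b[1];
            });
  out.erase(std::unique(out.begin(), out.end()), out.end());
  IntegerMatrix res((int)out.size(), 3);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i][0]; res(i, 1) = out[i][1]; res(i, 2) = out[i][2];
  }
  return res;
}

// longest l with hamming(prefix_l(a), prefix_l(b)) <= max_mm_rate * l
// [[Rcpp::export]]
int cpp_common_prefix(std::string a, std::string b, double max_mm_rate) {
  int n = (int)std::min(a.size(), b.size());
  int mm = 0, best = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) ++mm;
    if (mm <= max_mm_rate * (i + 1)) best = i + 1;
  }
  return best;
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  size_t n = std::min(a.size(), b.size());
  int d = (int)(std::max(a.size(), b.size()) - n);
  for (size_t i = 0; i < n; ++i) if (a[i] != b[i]) ++d;
  return d;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }
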