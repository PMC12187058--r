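// Hot paths shared by the encoder and the clustering stages:
//  - the versioned 32-bit LCG mapping an LT seed to (degree, neighbor set),
//  - bit/base conversion and biochemical constraint screening,
//  - unit-cost edit distance (banded with cutoff, and full DP with a
//    canonical backtrace decomposing the script into sub/del/ins),
//  - the greedy sphere-clustering sweep and the stage-3 center assignment.
#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---- deterministic LT selection PRNG (stable across releases: seeds live in DNA)

static inline uint32_t lcg_next(uint32_t s) {
  return 1664525u * s + 1013904223u; // Numerical-Recipes constants, mod 2^32
}
static inline double lcg_unif(uint32_t s) {
  return (static_cast<double>(s) + 0.5) / 4294967296.0;
}
// murmur3 finalizer: decorrelates sequential seeds before they feed the LCG
static inline uint32_t avalanche(uint32_t h) {
  h ^= h >> 16; h *= 0x85ebca6bu;
  h ^= h >> 13; h *= 0xc2b2ae35u;
  h ^= h >> 16;
  return h;
}

// Degree from the inverse CDF of `cumdist`, then Floyd's sampling of that many
// distinct segment indices in 1..K. Returns sorted 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_lt_neighbors(double seed, NumericVector cumdist, int K) {
  uint32_t s = avalanche(static_cast<uint32_t>(seed));
  s = lcg_next(s);
  double u = lcg_unif(s);
  int d = static_cast<int>(std::lower_bound(cumdist.begin(), cumdist.end(), u) -
                           cumdist.begin()) + 1;
  if (d > K) d = K;
  std::set<int> chosen;
  for (int j = K - d + 1; j <= K; ++j) {
    s = lcg_next(s);
    int r = 1 + static_cast<int>(lcg_unif(s) * j);
    if (r > j) r = j;
    if (chosen.count(r)) chosen.insert(j); else chosen.insert(r);
  }
  return IntegerVector(chosen.begin(), chosen.end());
}

// XOR (mod-2 sum) of the selected rows of a 0/1 integer matrix.
// [[Rcpp::export]]
IntegerVector cpp_xor_rows(IntegerMatrix bits, IntegerVector rows) {
  int nc = bits.ncol();
  IntegerVector out(nc);
  for (int r = 0; r < rows.size(); ++r) {
    int i = rows[r] - 1;
    if (i < 0 || i >= bits.nrow()) stop("row index out of range");
    for (int j = 0; j < nc; ++j) out[j] ^= bits(i, j);
  }
  return out;
}

// ---- bit <-> base mapping (A=00, C=01, G=10, T=11; big-endian within a pair)

static const char BASES[5] = "ACGT";

static inline int base_code(char b) {
  switch (b) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
std::string cpp_bits_to_bases(IntegerVector bits) {
  int n = bits.size();
  if (n % 2 != 0) stop("bit vector length must be even");
  std::string out(n / 2, 'A');
  for (int i = 0; i < n / 2; ++i) {
    int b1 = bits[2 * i], b2 = bits[2 * i + 1];
    if ((b1 != 0 && b1 != 1) || (b2 != 0 && b2 != 1)) stop("bits must be 0 or 1");
    out[i] = BASES[2 * b1 + b2];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_bases_to_bits(std::string bases) {
  int n = bases.size();
  IntegerVector out(2 * n);
  for (int i = 0; i < n; ++i) {
    int c = base_code(bases[i]);
    if (c < 0) stop("non-ACGT character at position %d", i + 1);
    out[2 * i] = c >> 1;
    out[2 * i + 1] = c & 1;
  }
  return out;
}

// 0 = pass, 1 = homopolymer run > max_run, 2 = GC% outside [gc_min, gc_max]
// [[Rcpp::export]]
int cpp_check_constraints(std::string s, int max_run, double gc_min, double gc_max) {
  int n = s.size();
  if (n == 0) stop("empty sequence");
  int run = 1, gc = 0;
  for (int i = 0; i < n; ++i) {
    char b = s[i];
    if (base_code(b) < 0) stop("non-ACGT character at position %d", i + 1);
    if (b == 'G' || b == 'C') ++gc;
    if (i > 0 && b == s[i - 1]) {
      if (++run > max_run) return 1;
    } else run = 1;
  }
  double pct = 100.0 * gc / n;
  if (pct < gc_min || pct > gc_max) return 2;
  return 0;
}

// ---- edit distance machinery

// Banded Ukkonen distance with cutoff: returns d if d <= tau, else tau+1.
static int banded_dist(const std::string& a, const std::string& b, int tau) {
  int n = a.size(), m = b.size();
  if (std::abs(n - m) > tau) return tau + 1;
  const int INF = tau + 1;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  for (int j = 0; j <= std::min(m, tau); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - tau), hi = std::min(m, i + tau);
    std::fill(cur.begin(), cur.end(), INF);
    if (i <= tau) cur[0] = i;
    int best = INF;
    for (int j = lo; j <= hi; ++j) {
      int d = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      if (d > INF) d = INF;
      cur[j] = d;
      if (d < best) best = d;
    }
    if (i <= tau && cur[0] < best) best = cur[0];
    if (best >= INF) return INF;
    std::swap(prev, cur);
  }
  return std::min(prev[m], INF);
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b, int tau) {
  if (tau < 0) tau = std::max(a.size(), b.size());
  return banded_dist(a, b, tau);
}

// Full DP with canonical backtrace. Tie order at each cell, walking back from
// (n, m): diagonal (match/substitution) first, then deletion (gap in b), then
// insertion (gap in a). Orientation is a -> b, so e_del - e_ins = |a| - |b|.
static void edit_backtrace(const std::string& a, const std::string& b,
                           std::string& ops) {
  int n = a.size(), m = b.size();
  std::vector<int> D((n + 1) * (m + 1));
  int w = m + 1;
  for (int i = 0; i <= n; ++i) D[i * w] = i;
  for (int j = 0; j <= m; ++j) D[j] = j;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int d = D[(i - 1) * w + j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      d = std::min(d, D[(i - 1) * w + j] + 1);
      d = std::min(d, D[i * w + j - 1] + 1);
      D[i * w + j] = d;
    }
  int i = n, j = m;
  ops.clear();
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i * w + j] == D[(i - 1) * w + j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0)) {
      ops.push_back(a[i - 1] == b[j - 1] ? 'M' : 'S');
      --i; --j;
    } else if (i > 0 && D[i * w + j] == D[(i - 1) * w + j] + 1) {
      ops.push_back('D');
      --i;
    } else {
      ops.push_back('I');
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
}

// [[Rcpp::export]]
IntegerVector cpp_edit_counts(std::string a, std::string b) {
  std::string ops;
  edit_backtrace(a, b, ops);
  int s = 0, d = 0, ins = 0;
  for (char c : ops) {
    if (c == 'S') ++s; else if (c == 'D') ++d; else if (c == 'I') ++ins;
  }
  return IntegerVector::create(_["sub"] = s, _["del"] = d, _["ins"] = ins);
}

// Pairwise global alignment of (center, member) under the same canonical
// backtrace; returns the two gapped strings.
// [[Rcpp::export]]
CharacterVector cpp_align_pair(std::string a, std::string b) {
  std::string ops;
  edit_backtrace(a, b, ops);
  std::string ga, gb;
  ga.reserve(ops.size()); gb.reserve(ops.size());
  size_t i = 0, j = 0;
  for (char c : ops) {
    if (c == 'M' || c == 'S')      { ga.push_back(a[i++]); gb.push_back(b[j++]); }
    else if (c == 'D')             { ga.push_back(a[i++]); gb.push_back('-'); }
    else /* 'I' */                 { ga.push_back('-');    gb.push_back(b[j++]); }
  }
  return CharacterVector::create(ga, gb);
}

// Greedy sphere sweep over abundance-sorted unique sequences: each sequence
// joins the first earlier-created center within edit distance tau, else opens
// a new center. Returns, per sequence, the 1-based index (into `seqs`) of its
// center.
// [[Rcpp::export]]
IntegerVector cpp_sphere_sweep(CharacterVector seqs, int tau) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<int> centers;
  std::vector<std::string> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    int hit = 0;
    for (size_t c = 0; c < centers.size(); ++c) {
      int ci = centers[c];
      if (banded_dist(sv[ci], sv[i], tau) <= tau) { hit = ci + 1; break; }
    }
    if (hit == 0) { centers.push_back(i); hit = i + 1; }
    assign[i] = hit;
  }
  return assign;
}

// Stage-3 assignment: for each query (an abnormal-length read), the center
// (an EDOL read) minimizing the length-adjusted edit distance, subject to
// adjusted <= tau_adj and optional per-type caps (cap < 0 disables a cap).
// Ties go to the smaller center index. Returns nq x 5:
// center index (0 = unassigned), adjusted distance, e_sub, e_del, e_ins.
// [[Rcpp::export]]
IntegerMatrix cpp_stage3_assign(CharacterVector centers, CharacterVector queries,
                                int tau_adj, int cap_sub, int cap_del, int cap_ins) {
  int nc = centers.size(), nq = queries.size();
  std::vector<std::string> cv(nc), qv(nq);
  for (int i = 0; i < nc; ++i) cv[i] = as<std::string>(centers[i]);
  for (int i = 0; i < nq; ++i) qv[i] = as<std::string>(queries[i]);
  IntegerMatrix out(nq, 5);
  for (int q = 0; q < nq; ++q) {
    int best_c = 0, best_adj = tau_adj + 1;
    int best_s = 0, best_d = 0, best_i = 0;
    for (int c = 0; c < nc; ++c) {
      int dlen = std::abs((int)cv[c].size() - (int)qv[q].size());
      int cutoff = tau_adj + dlen;
      int d = banded_dist(cv[c], qv[q], cutoff);
      if (d > cutoff) continue;
      int adj = d - dlen;
      if (adj > tau_adj || adj >= best_adj) continue;
      std::string ops;
      edit_backtrace(cv[c], qv[q], ops);
      int s = 0, del = 0, ins = 0;
      for (char ch : ops) {
        if (ch == 'S') ++s; else if (ch == 'D') ++del; else if (ch == 'I') ++ins;
      }
      if (cap_sub >= 0 && s > cap_sub) continue;
      if (cap_del >= 0 && del > cap_del) continue;
      if (cap_ins >= 0 && ins > cap_ins) continue;
      best_c = c + 1; best_adj = adj; best_s = s; best_d = del; best_i = ins;
    }
    out(q, 0) = best_c;
    out(q, 1) = best_c ? best_adj : NA_INTEGER;
    out(q, 2) = best_s; out(q, 3) = best_d; out(q, 4) = best_i;
  }
  return out;
}
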