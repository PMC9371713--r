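// Triad (3-node connected subgraph) machinery for directed graphs, plus the
// degree-preserving edge-switching and census-preserving annealing null models.
//
// A triple occupying positions (1,2,3) is encoded in 6 bits:
//   bit0: 1->2, bit1: 2->1, bit2: 1->3, bit3: 3->1, bit4: 2->3, bit5: 3->2.
// Self-loops are ignored by the census (classes are defined on off-diagonal
// adjacency) and are held fixed by both randomizers.

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int PERMS[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

static int canon_tab[64];
static bool conn_tab[64];
static uint8_t canon_perm_mask[64]; // bit p set if PERMS[p] achieves the min
static bool tabs_ready = false;

static inline int code_bit(int code, int i, int j) {
  // i, j in {0,1,2}; returns adjacency bit i->j from a 6-bit code
  static const int pos[3][3] = {{-1, 0, 2}, {1, -1, 4}, {3, 5, -1}};
  return (code >> pos[i][j]) & 1;
}

static inline int permute_code(int code, const int* p) {
  static const int pos[3][3] = {{-1, 0, 2}, {1, -1, 4}, {3, 5, -1}};
  int out = 0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (i != j && code_bit(code, p[i], p[j]))
        out |= 1 << pos[i][j];
  return out;
}

// sort key making bit0 (edge 1->2) the most significant bit, so that integer
// order of keys matches lexicographic order of the bit strings used by the
// R-level canonical_form()
static inline int revkey(int code) {
  int k = 0;
  for (int b = 0; b < 6; ++b) k |= ((code >> b) & 1) << (5 - b);
  return k;
}

static void init_tabs() {
  if (tabs_ready) return;
  for (int c = 0; c < 64; ++c) {
    int best = 64, bestcode = 0;
    uint8_t mask = 0;
    for (int p = 0; p < 6; ++p) {
      int pc = permute_code(c, PERMS[p]);
      int key = revkey(pc);
      if (key < best) { best = key; bestcode = pc; mask = (uint8_t)(1 << p); }
      else if (key == best) mask |= (uint8_t)(1 << p);
    }
    canon_tab[c] = bestcode;
    canon_perm_mask[c] = mask;
    int d12 = ((c >> 0) | (c >> 1)) & 1;
    int d13 = ((c >> 2) | (c >> 3)) & 1;
    int d23 = ((c >> 4) | (c >> 5)) & 1;
    conn_tab[c] = (d12 + d13 + d23) >= 2;
  }
  tabs_ready = true;
}

// --- adjacency bitset -------------------------------------------------------

struct BitAdj {
  int n, W;
  std::vector<uint64_t> bits;
  BitAdj(int n_) : n(n_), W((n_ + 63) / 64), bits((size_t)n_ * ((n_ + 63) / 64), 0) {}
  inline bool get(int i, int j) const {
    return (bits[(size_t)i * W + (j >> 6)] >> (j & 63)) & 1ull;
  }
  inline void set(int i, int j) { bits[(size_t)i * W + (j >> 6)] |= 1ull << (j & 63); }
  inline void clr(int i, int j) { bits[(size_t)i * W + (j >> 6)] &= ~(1ull << (j & 63)); }
};

static inline int triple_code(const BitAdj& A, int a, int b, int c) {
  int code = 0;
  if (A.get(a, b)) code |= 1;
  if (A.get(b, a)) code |= 2;
  if (A.get(a, c)) code |= 4;
  if (A.get(c, a)) code |= 8;
  if (A.get(b, c)) code |= 16;
  if (A.get(c, b)) code |= 32;
  return code;
}

static BitAdj build_adj(int n, const IntegerMatrix& edges) {
  BitAdj A(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int s = edges(e, 0) - 1, t = edges(e, 1) - 1;
    if (s < 0 || s >= n || t < 0 || t >= n) stop("edge endpoint out of range");
    A.set(s, t);
  }
  return A;
}

static std::vector<std::vector<int>> skeleton_neighbors(int n, const BitAdj& A) {
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A.get(i, j) || A.get(j, i)) { nb[i].push_back(j); nb[j].push_back(i); }
  return nb;
}

// enumerate each weakly-connected triple exactly once; call f(a, b, c) with
// a < b < c
template <typename F>
static void for_each_connected_triple(int n, const BitAdj& A,
                                      const std::vector<std::vector<int>>& nb,
                                      F f) {
  for (int m = 0; m < n; ++m) {
    const std::vector<int>& N = nb[m];
    for (size_t i = 0; i < N.size(); ++i)
      for (size_t j = i + 1; j < N.size(); ++j) {
        int v = N[i], w = N[j];
        bool vw = A.get(v, w) || A.get(w, v);
        if (vw && !(m < v && m < w)) continue; // triangle: count at min node
        int a = m, b = v, c = w;
        if (a > b) std::swap(a, b);
        if (b > c) std::swap(b, c);
        if (a > b) std::swap(a, b);
        f(a, b, c);
      }
  }
}

// [[Rcpp::export]]
List cpp_triad_census(int n, IntegerMatrix edges, bool instances = false) {
  init_tabs();
  BitAdj A = build_adj(n, edges);
  std::vector<std::vector<int>> nb = skeleton_neighbors(n, A);
  IntegerVector counts(64);
  std::vector<int> inst;
  for_each_connected_triple(n, A, nb, [&](int a, int b, int c) {
    int code = triple_code(A, a, b, c);
    if (!conn_tab[code]) return;
    counts[canon_tab[code]]++;
    if (instances) {
      // order nodes by canonical position; among automorphic orderings take
      // the lexicographically smallest node tuple
      int nodes[3] = {a, b, c};
      int best[3] = {-1, -1, -1};
      uint8_t mask = canon_perm_mask[code];
      for (int p = 0; p < 6; ++p) {
        if (!(mask & (1 << p))) continue;
        int cand[3] = {nodes[PERMS[p][0]], nodes[PERMS[p][1]], nodes[PERMS[p][2]]};
        if (best[0] < 0 || std::lexicographical_compare(cand, cand + 3, best, best + 3))
          std::copy(cand, cand + 3, best);
      }
      inst.push_back(best[0] + 1);
      inst.push_back(best[1] + 1);
      inst.push_back(best[2] + 1);
      inst.push_back(canon_tab[code]);
    }
  });
  List out = List::create(_["counts"] = counts);
  if (instances) {
    int ni = (int)(inst.size() / 4);
    IntegerMatrix M(ni, 4);
    for (int i = 0; i < ni; ++i)
      for (int j = 0; j < 4; ++j) M(i, j) = inst[4 * i + j];
    out["instances"] = M;
  }
  return out;
}

// [[Rcpp::export]]
int cpp_mutual_count(int n, IntegerMatrix edges) {
  BitAdj A = build_adj(n, edges);
  int m = 0;
  for (int e = 0; e < edges.nrow(); ++e) {
    int s = edges(e, 0) - 1, t = edges(e, 1) - 1;
    if (s < t && A.get(t, s)) ++m;
  }
  return m;
}

// --- degree-preserving switching -------------------------------------------

struct EdgePool {
  std::vector<std::pair<int, int>> ed; // non-loop edges
  std::vector<std::pair<int, int>> loops;
};

static EdgePool split_edges(const IntegerMatrix& edges) {
  EdgePool P;
  for (int e = 0; e < edges.nrow(); ++e) {
    int s = edges(e, 0) - 1, t = edges(e, 1) - 1;
    if (s == t) P.loops.push_back({s, t});
    else P.ed.push_back({s, t});
  }
  return P;
}

static IntegerMatrix pool_to_matrix(const EdgePool& P) {
  int m = (int)(P.ed.size() + P.loops.size());
  IntegerMatrix M(m, 2);
  int r = 0;
  for (auto& e : P.ed) { M(r, 0) = e.first + 1; M(r, 1) = e.second + 1; ++r; }
  for (auto& e : P.loops) { M(r, 0) = e.first + 1; M(r, 1) = e.second + 1; ++r; }
  return M;
}

// attempt one double-edge swap; returns true and fills indices/endpoints on a
// structurally valid proposal
static bool propose_swap(std::mt19937& rng, const EdgePool& P, const BitAdj& A,
                         int& i1, int& i2, int& a, int& b, int& c, int& d) {
  size_t m = P.ed.size();
  if (m < 2) return false;
  std::uniform_int_distribution<size_t> U(0, m - 1);
  i1 = (int)U(rng); i2 = (int)U(rng);
  if (i1 == i2) return false;
  a = P.ed[i1].first; b = P.ed[i1].second;
  c = P.ed[i2].first; d = P.ed[i2].second;
  if (a == c || b == d || a == d || c == b) return false;
  if (A.get(a, d) || A.get(c, b)) return false;
  return true;
}

static void apply_swap(EdgePool& P, BitAdj& A, int i1, int i2,
                       int a, int b, int c, int d) {
  A.clr(a, b); A.clr(c, d); A.set(a, d); A.set(c, b);
  P.ed[i1] = {a, d};
  P.ed[i2] = {c, b};
}

// [[Rcpp::export]]
IntegerMatrix cpp_rewire_degseq(int n, IntegerMatrix edges, int nswap, int seed) {
  EdgePool P = split_edges(edges);
  BitAdj A = build_adj(n, edges);
  std::mt19937 rng((uint32_t)seed);
  long attempts = 0, maxatt = 200L * (nswap > 0 ? nswap : 1) + 1000L;
  int done = 0;
  while (done < nswap && attempts < maxatt) {
    ++attempts;
    int i1, i2, a, b, c, d;
    if (!propose_swap(rng, P, A, i1, i2, a, b, c, d)) continue;
    apply_swap(P, A, i1, i2, a, b, c, d);
    ++done;
  }
  return pool_to_matrix(P);
}

// --- census-preserving annealing -------------------------------------------

struct CensusState {
  BitAdj A;
  std::vector<int> counts;   // per canonical code, connected classes only
  int mut;
  double energy;
  const std::vector<int>& target;
  int mut_target;
  CensusState(BitAdj A_, const std::vector<int>& target_, int mut_target_)
      : A(std::move(A_)), counts(64, 0), mut(0), energy(0),
        target(target_), mut_target(mut_target_) {}
};

static std::vector<int> census_counts(int n, const BitAdj& A) {
  std::vector<int> counts(64, 0);
  std::vector<std::vector<int>> nb = skeleton_neighbors(n, A);
  for_each_connected_triple(n, A, nb, [&](int a, int b, int c) {
    int code = triple_code(A, a, b, c);
    if (conn_tab[code]) counts[canon_tab[code]]++;
  });
  return counts;
}

// class-count delta accumulator for one proposed swap: at most a handful of
// classes are touched, so deltas are kept in a fixed array plus touched list
struct DeltaAcc {
  int delta[64];
  bool marked[64];
  int touched[64];
  int ntouched = 0;
  DeltaAcc() {
    std::fill(delta, delta + 64, 0);
    std::fill(marked, marked + 64, false);
  }
  inline void add(int cls, int d) {
    if (!marked[cls]) { marked[cls] = true; touched[ntouched++] = cls; }
    delta[cls] += d;
  }
  inline void reset() {
    for (int i = 0; i < ntouched; ++i) {
      delta[touched[i]] = 0;
      marked[touched[i]] = false;
    }
    ntouched = 0;
  }
};

static inline void acc_code_change(DeltaAcc& acc, int before, int after) {
  if (before == after) return;
  if (conn_tab[before]) acc.add(canon_tab[before], -1);
  if (conn_tab[after]) acc.add(canon_tab[after], +1);
}

// [[Rcpp::export]]
List cpp_rewire_census(int n, IntegerMatrix edges, int seed,
                       int scramble_factor = 10, double t0 = -1,
                       double cool = 0.9995, int cool_block = 50,
                       double tmin = 1e-3, double reheat_to = -1,
                       long maxit = 2000000, int max_reheats = 50) {
  init_tabs();

  // target census from the original network
  BitAdj A0 = build_adj(n, edges);
  std::vector<int> target = census_counts(n, A0);
  int mut_target = 0;
  {
    EdgePool P0 = split_edges(edges);
    for (auto& e : P0.ed)
      if (e.first < e.second && A0.get(e.second, e.first)) ++mut_target;
  }

  // phase 1: scramble by plain switching
  int m = 0;
  for (int e = 0; e < edges.nrow(); ++e)
    if (edges(e, 0) != edges(e, 1)) ++m;
  IntegerMatrix scrambled =
      cpp_rewire_degseq(n, edges, scramble_factor * (m > 0 ? m : 1), seed);

  EdgePool P = split_edges(scrambled);
  BitAdj A = build_adj(n, scrambled);
  BitAdj AT(n); // transpose, for fast skeleton-neighborhood scans
  for (auto& e : P.ed) AT.set(e.second, e.first);
  for (auto& e : P.loops) AT.set(e.first, e.first);
  std::vector<int> counts = census_counts(n, A);
  int mut = 0;
  for (auto& e : P.ed)
    if (e.first < e.second && A.get(e.second, e.first)) ++mut;

  double E = 0;
  for (int c = 0; c < 64; ++c) E += std::abs(counts[c] - target[c]);
  E += std::abs(mut - mut_target);

  std::mt19937 rng((uint32_t)seed ^ 0x9e3779b9u);
  std::uniform_real_distribution<double> UR(0.0, 1.0);

  double T = (t0 > 0) ? t0 : std::max(2.0, E / 8.0);
  const double T0 = T;
  if (reheat_to <= 0) reheat_to = std::max(1.0, T0 / 4.0);
  int reheats = 0;
  long iter = 0;
  const int W = A.W;
  DeltaAcc acc;

  // basin hopping: when the best energy has not improved for a while, force
  // a short burst of unconditional swaps to escape the current plateau
  double bestE = E;
  long since_best = 0;
  const long stag_limit = 150000;
  int kick_remaining = 0;

  while (E > 0 && iter < maxit) {
    ++iter;
    if (iter % cool_block == 0) {
      T *= cool;
      if (T < tmin) {
        if (++reheats > max_reheats) break;
        T = reheat_to;
      }
    }
    if (E < bestE) { bestE = E; since_best = 0; }
    if (++since_best > stag_limit) {
      kick_remaining = 10;
      if (T < 0.5) T = 0.5;
      since_best = 0;
    }
    int i1, i2, a, b, c, d;
    if (!propose_swap(rng, P, A, i1, i2, a, b, c, d)) continue;

    // evaluate the census delta without touching state. The swap removes
    // edges a->b, c->d and adds a->d, c->b; each affected triple contains
    // exactly one changed node pair (plus the four triples inside
    // {a,b,c,d}, handled separately). For a triple (f, t, w) ordered with
    // the changed pair first, the changed edge f->t is bit 0 of the code.
    acc.reset();
    const int chg[4][3] = { // {from, to, gained?}
      {a, b, 0}, {c, d, 0}, {a, d, 1}, {c, b, 1}};
    for (int ci = 0; ci < 4; ++ci) {
      int f = chg[ci][0], t = chg[ci][1], gain = chg[ci][2];
      // third nodes connected to f or t (in either direction)
      const uint64_t* rf = &A.bits[(size_t)f * W];
      const uint64_t* rft = &AT.bits[(size_t)f * W];
      const uint64_t* rt = &A.bits[(size_t)t * W];
      const uint64_t* rtt = &AT.bits[(size_t)t * W];
      for (int wd = 0; wd < W; ++wd) {
        uint64_t bitsw = rf[wd] | rft[wd] | rt[wd] | rtt[wd];
        while (bitsw) {
          int w = wd * 64 + __builtin_ctzll(bitsw);
          bitsw &= bitsw - 1;
          if (w == a || w == b || w == c || w == d) continue;
          int code = triple_code(A, f, t, w);
          int after = gain ? (code | 1) : (code & ~1);
          acc_code_change(acc, code, after);
        }
      }
    }
    // the four triples inside {a, b, c, d}; bits follow triple_code order
    {
      int code, after;
      code = triple_code(A, a, b, d);      // changes: -(a->b)=b0, +(a->d)=b2
      after = (code & ~1) | 4;
      acc_code_change(acc, code, after);
      code = triple_code(A, a, b, c);      // changes: -(a->b)=b0, +(c->b)=b5
      after = (code & ~1) | 32;
      acc_code_change(acc, code, after);
      code = triple_code(A, a, c, d);      // changes: -(c->d)=b4, +(a->d)=b2
      after = (code & ~16) | 4;
      acc_code_change(acc, code, after);
      code = triple_code(A, b, c, d);      // changes: -(c->d)=b4, +(c->b)=b1
      after = (code & ~16) | 2;
      acc_code_change(acc, code, after);
    }
    int dmut = 0;
    if (A.get(b, a)) --dmut; // {a,b} was mutual, loses a->b
    if (A.get(d, c)) --dmut;
    if (A.get(d, a)) ++dmut; // {a,d} becomes mutual if d->a present
    if (A.get(b, c)) ++dmut;

    double Enew = E;
    Enew -= std::abs(mut - mut_target);
    Enew += std::abs(mut + dmut - mut_target);
    for (int i = 0; i < acc.ntouched; ++i) {
      int cc = acc.touched[i];
      Enew -= std::abs(counts[cc] - target[cc]);
      Enew += std::abs(counts[cc] + acc.delta[cc] - target[cc]);
    }

    double dE = Enew - E;
    bool force = kick_remaining > 0;
    if (force) --kick_remaining;
    if (force || dE <= 0 || UR(rng) < std::exp(-dE / T)) {
      E = Enew;
      mut += dmut;
      for (int i = 0; i < acc.ntouched; ++i) {
        counts[acc.touched[i]] += acc.delta[acc.touched[i]];
      }
      apply_swap(P, A, i1, i2, a, b, c, d);
      AT.clr(b, a); AT.clr(d, c); AT.set(d, a); AT.set(b, c);
    }
  }

  return List::create(_["edges"] = pool_to_matrix(P),
                      _["energy"] = E,
                      _["iterations"] = (double)iter,
                      _["converged"] = (E == 0));
}

// [[Rcpp::export]]
IntegerVector cpp_canon_codes() {
  init_tabs();
  IntegerVector out(64);
  for (int c = 0; c < 64; ++c) out[c] = canon_tab[c];
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_connected_codes() {
  init_tabs();
  LogicalVector out(64);
  for (int c = 0; c < 64; ++c) out[c] = conn_tab[c];
  return out;
}
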