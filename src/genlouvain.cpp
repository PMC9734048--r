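#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Greedy two-phase maximization of multilayer modularity on a temporal
// multilayer network: W intralayer weight matrices (R x R, zero diagonal)
// plus identity-node coupling of weight omega between ordinally adjacent
// layers.  Quality:
//   Q = (1/2mu) * sum_{ijsr} [ (A_ijs - gamma k_is k_js / 2m_s) d_sr
//                              + d_ij C_jsr ] d(g_is, g_jr)
// where 2mu is the total node-layer strength including coupling.
//
// Level 0 sweeps the node-layer copies directly, using sparse intralayer
// edge lists plus per-layer community strength totals for the (dense) null
// term.  Aggregated levels run on a sparse community-by-community matrix
// with the null term folded into the entries.  All randomness comes from an
// own splitmix64 generator so results are bit-reproducible across
// platforms for a given seed.

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // deterministic Fisher-Yates shuffle
  void shuffle(std::vector<int>& v) {
    for (size_t i = v.size(); i > 1; --i) {
      size_t j = next() % i;
      std::swap(v[i - 1], v[j]);
    }
  }
};

const double GAIN_EPS = 1e-12;

typedef std::vector<std::vector<std::pair<int, double>>> SparseRows;

// Compact labels to 0..C-1 preserving first-appearance order.
int relabel(std::vector<int>& lab) {
  std::vector<int> map(lab.size(), -1);
  int c = 0;
  for (size_t i = 0; i < lab.size(); ++i) {
    if (map[lab[i]] < 0) map[lab[i]] = c++;
    lab[i] = map[lab[i]];
  }
  return c;
}

// Scratch accumulator over community ids with O(1) membership tests.
struct Scratch {
  std::vector<double> val;
  std::vector<char> seen;
  std::vector<int> touched;
  explicit Scratch(int n) : val(n, 0.0), seen(n, 0) { touched.reserve(256); }
  inline void add(int c, double x) {
    if (!seen[c]) {
      seen[c] = 1;
      touched.push_back(c);
    }
    val[c] += x;
  }
  inline void reset() {
    for (int c : touched) {
      val[c] = 0.0;
      seen[c] = 0;
    }
    touched.clear();
  }
};

// One move phase on a sparse symmetric matrix (self-loops allowed, ignored
// for moves).  Entries already contain the null-model part.  Returns true
// if any node changed community.
bool phase_sparse(const SparseRows& rows, std::vector<int>& lab,
                  SplitMix64& rng) {
  int C = (int)rows.size();
  std::vector<int> order(C);
  for (int i = 0; i < C; ++i) order[i] = i;
  Scratch sc(C);
  bool any_move = false;
  bool improved = true;
  while (improved) {
    improved = false;
    rng.shuffle(order);
    for (int oi = 0; oi < C; ++oi) {
      int v = order[oi];
      int cur = lab[v];
      for (const auto& e : rows[v]) {
        if (e.first == v) continue;
        sc.add(lab[e.first], e.second);
      }
      sc.add(cur, 0.0);
      int best = cur;
      double best_gain = 0.0;
      for (int c : sc.touched) {
        if (c == cur) continue;
        double gain = sc.val[c] - sc.val[cur];
        if (gain > best_gain + GAIN_EPS) {
          best_gain = gain;
          best = c;
        }
      }
      sc.reset();
      if (best != cur) {
        lab[v] = best;
        improved = true;
        any_move = true;
      }
    }
  }
  return any_move;
}

// Aggregate a sparse matrix by community labels (labels must be 0..C2-1).
SparseRows aggregate_sparse(const SparseRows& rows, const std::vector<int>& lab,
                            int C2) {
  std::vector<std::vector<int>> members(C2);
  for (size_t v = 0; v < rows.size(); ++v) members[lab[v]].push_back((int)v);
  SparseRows out(C2);
  Scratch sc(C2);
  for (int c = 0; c < C2; ++c) {
    for (int v : members[c])
      for (const auto& e : rows[v]) sc.add(lab[e.first], e.second);
    out[c].reserve(sc.touched.size());
    for (int c2 : sc.touched) out[c].push_back({c2, sc.val[c2]});
    sc.reset();
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List genlouvain_cpp(NumericVector layers, int n_regions, int n_layers,
                    double gamma, double omega, int seed) {
  const int R = n_regions, W = n_layers;
  const size_t N = (size_t)R * W;
  const double* A = REAL(layers);  // R x R x W

  // per-layer strengths and totals
  std::vector<double> k((size_t)R * W, 0.0), twom(W, 0.0);
  for (int s = 0; s < W; ++s) {
    const double* As = A + (size_t)s * R * R;
    for (int i = 0; i < R; ++i) {
      double ki = 0.0;
      for (int j = 0; j < R; ++j) ki += As[(size_t)j * R + i];
      k[(size_t)s * R + i] = ki;
      twom[s] += ki;
    }
  }
  double twomu = 0.0;
  for (int s = 0; s < W; ++s) twomu += twom[s];
  twomu += 2.0 * omega * R * (W - 1);
  if (twomu <= 0.0)
    stop("multilayer network has zero total weight and zero coupling");

  SplitMix64 rng((uint64_t)(uint32_t)seed * 0x9e3779b97f4a7c15ULL + 1ULL);

  // sparse intralayer adjacency
  SparseRows adj(N);
  for (int s = 0; s < W; ++s) {
    const double* As = A + (size_t)s * R * R;
    for (int i = 0; i < R; ++i)
      for (int j = 0; j < R; ++j) {
        double a = As[(size_t)j * R + i];
        if (j != i && a != 0.0)
          adj[(size_t)s * R + i].push_back({s * R + j, a});
      }
  }

  // ---- level 0: move phase directly on the layer stack -------------------
  // candidate moves are to communities adjacent via an intralayer edge or
  // an interlayer coupling; per-layer community strength totals give the
  // null-model part of each gain in O(1)
  std::vector<int> lab(N);
  for (size_t v = 0; v < N; ++v) lab[v] = (int)v;
  std::vector<int> order(N);
  for (size_t v = 0; v < N; ++v) order[v] = (int)v;
  {
    std::vector<double> tot((size_t)W * N, 0.0);  // tot[s*N + community]
    for (size_t v = 0; v < N; ++v) tot[(size_t)(v / R) * N + v] = k[v];
    Scratch sc((int)N);
    bool improved = true;
    while (improved) {
      improved = false;
      rng.shuffle(order);
      for (size_t oi = 0; oi < N; ++oi) {
        int v = order[oi];
        int s = v / R;
        int cur = lab[v];
        double kv = k[v];
        for (const auto& e : adj[v]) sc.add(lab[e.first], e.second);
        if (omega != 0.0) {
          if (s > 0) sc.add(lab[(size_t)v - R], omega);
          if (s < W - 1) sc.add(lab[(size_t)v + R], omega);
        }
        sc.add(cur, 0.0);
        double gk = (twom[s] > 0.0) ? gamma * kv / twom[s] : 0.0;
        const double* tots = &tot[(size_t)s * N];
        double score_cur = sc.val[cur] - gk * (tots[cur] - kv);
        int best = cur;
        double best_gain = 0.0;
        for (int c : sc.touched) {
          if (c == cur) continue;
          double gain = (sc.val[c] - gk * tots[c]) - score_cur;
          if (gain > best_gain + GAIN_EPS) {
            best_gain = gain;
            best = c;
          }
        }
        sc.reset();
        if (best != cur) {
          lab[v] = best;
          tot[(size_t)s * N + cur] -= kv;
          tot[(size_t)s * N + best] += kv;
          improved = true;
        }
      }
    }
  }
  int C = relabel(lab);

  // ---- aggregate into a sparse community matrix with the null folded in --
  // per-layer community membership and strength totals drive the null term:
  // communities co-present in a layer are coupled by -gamma*tot_c1*tot_c2/2m_s
  SparseRows M;
  {
    std::vector<std::vector<int>> members(C);
    for (size_t v = 0; v < N; ++v) members[lab[v]].push_back((int)v);
    // per-layer present communities with totals
    std::vector<std::vector<std::pair<int, double>>> present(W);
    {
      std::vector<double> tot_s(C, 0.0);
      std::vector<int> pr;
      pr.reserve(R);
      for (int s = 0; s < W; ++s) {
        pr.clear();
        for (int i = 0; i < R; ++i) {
          size_t v = (size_t)s * R + i;
          int ci = lab[v];
          if (tot_s[ci] == 0.0 && k[v] != 0.0) pr.push_back(ci);
          tot_s[ci] += k[v];
        }
        present[s].reserve(pr.size());
        for (int c : pr) {
          present[s].push_back({c, tot_s[c]});
          tot_s[c] = 0.0;
        }
      }
    }
    // invert: layers each community is present in
    std::vector<std::vector<std::pair<int, double>>> layers_of(C);
    for (int s = 0; s < W; ++s)
      for (const auto& pc : present[s])
        layers_of[pc.first].push_back({s, pc.second});

    M.resize(C);
    Scratch sc(C);
    for (int c = 0; c < C; ++c) {
      for (int v : members[c]) {
        for (const auto& e : adj[v]) sc.add(lab[e.first], e.second);
        if (omega != 0.0) {
          int s = v / R;
          if (s > 0) sc.add(lab[(size_t)v - R], omega);
          if (s < W - 1) sc.add(lab[(size_t)v + R], omega);
        }
      }
      for (const auto& st : layers_of[c]) {
        int s = st.first;
        if (twom[s] <= 0.0) continue;
        double factor = gamma * st.second / twom[s];
        for (const auto& pc : present[s]) sc.add(pc.first, -factor * pc.second);
      }
      M[c].reserve(sc.touched.size());
      for (int c2 : sc.touched) M[c].push_back({c2, sc.val[c2]});
      sc.reset();
    }
  }

  // ---- higher levels: move + aggregate until quality stops improving -----
  while (true) {
    std::vector<int> lab2(C);
    for (int c = 0; c < C; ++c) lab2[c] = c;
    bool moved = phase_sparse(M, lab2, rng);
    if (!moved) break;
    int C2 = relabel(lab2);
    for (size_t v = 0; v < N; ++v) lab[v] = lab2[lab[v]];
    M = aggregate_sparse(M, lab2, C2);
    C = C2;
  }

  // quality: communities are single super-nodes now; sum the self-loops
  double qsum = 0.0;
  for (int c = 0; c < C; ++c)
    for (const auto& e : M[c])
      if (e.first == c) qsum += e.second;
  double quality = qsum / twomu;

  IntegerMatrix out(R, W);
  for (int s = 0; s < W; ++s)
    for (int i = 0; i < R; ++i) out(i, s) = lab[(size_t)s * R + i] + 1;
  return List::create(_["labels"] = out, _["quality"] = quality,
                      _["n_communities"] = C);
}
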