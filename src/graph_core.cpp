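// Core graph kernels for binary undirected networks.
// Hand-rolled bitset BFS / Louvain / rewiring so that the evolutionary loop
// can evaluate ~1e5-1e6 candidate networks without per-call graph-object
// overhead. Adjacency rows are packed into 64-bit words; BFS expands whole
// frontiers with word OR/AND operations and triangle counts use popcount.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (splitmix64; std:: distributions are implementation-
// defined, so only raw streams + modulo/scale are used).
// ---------------------------------------------------------------------------
struct RngState {
  uint64_t s;
  explicit RngState(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
  template <typename T> void shuffle(std::vector<T>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

static inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}
static inline int ctz64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_ctzll(x);
#else
  int c = 0; while (!(x & 1)) { x >>= 1; ++c; } return c;
#endif
}

// ---------------------------------------------------------------------------
// Bit-packed adjacency
// ---------------------------------------------------------------------------
struct BitGraph {
  int n, W;
  std::vector<uint64_t> rows; // n * W words
  std::vector<int> deg;
  void init(int n_) {
    n = n_;
    W = (n + 63) / 64;
    rows.assign((size_t)n * W, 0ULL);
    deg.assign(n, 0);
  }
  inline uint64_t* row(int i) { return rows.data() + (size_t)i * W; }
  inline const uint64_t* row(int i) const {
    return rows.data() + (size_t)i * W;
  }
  inline void add_edge(int i, int j) {
    row(i)[j >> 6] |= 1ULL << (j & 63);
    row(j)[i >> 6] |= 1ULL << (i & 63);
    ++deg[i]; ++deg[j];
  }
};

static void bitgraph_from_adj(const IntegerMatrix& adj, BitGraph& g) {
  int n = adj.nrow();
  g.init(n);
  for (int j = 0; j < n; ++j)
    for (int i = j + 1; i < n; ++i)
      if (adj(i, j) != 0) g.add_edge(i, j);
}

// BFS level sums from src, optionally restricted to a node mask (sub != null).
// Accumulates sum(1/d), sum(d) and reach count over nodes reached from src.
static inline void bfs_sums(const BitGraph& g, int src, const uint64_t* sub,
                            uint64_t* visited, uint64_t* frontier,
                            uint64_t* nextf,
                            double& inv_sum, double& d_sum, double& reach) {
  int W = g.W;
  for (int w = 0; w < W; ++w) { visited[w] = 0; frontier[w] = 0; }
  visited[src >> 6] = frontier[src >> 6] = 1ULL << (src & 63);
  int d = 0;
  while (true) {
    for (int w = 0; w < W; ++w) nextf[w] = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t x = frontier[w];
      while (x) {
        int u = (w << 6) + ctz64(x);
        x &= x - 1;
        const uint64_t* r = g.row(u);
        for (int v = 0; v < W; ++v) nextf[v] |= r[v];
      }
    }
    ++d;
    int c = 0;
    for (int w = 0; w < W; ++w) {
      nextf[w] &= ~visited[w];
      if (sub) nextf[w] &= sub[w];
      visited[w] |= nextf[w];
      c += popcnt64(nextf[w]);
    }
    if (c == 0) break;
    inv_sum += (double)c / d;
    d_sum += (double)c * d;
    reach += c;
    std::swap(frontier, nextf);
  }
}

static double global_eff_bits(const BitGraph& g) {
  int n = g.n;
  if (n < 2) return 0.0;
  std::vector<uint64_t> vis(g.W), fr(g.W), nx(g.W);
  double inv = 0, ds = 0, rc = 0;
  for (int src = 0; src < n; ++src)
    bfs_sums(g, src, nullptr, vis.data(), fr.data(), nx.data(), inv, ds, rc);
  return inv / ((double)n * (n - 1));
}

// sum of shortest-path lengths and count of reachable ordered pairs
static void path_sums_bits(const BitGraph& g, double& d_sum, double& reach) {
  std::vector<uint64_t> vis(g.W), fr(g.W), nx(g.W);
  double inv = 0;
  d_sum = 0; reach = 0;
  for (int src = 0; src < g.n; ++src)
    bfs_sums(g, src, nullptr, vis.data(), fr.data(), nx.data(),
             inv, d_sum, reach);
}

static double clustering_bits(const BitGraph& g) {
  int n = g.n, W = g.W;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = g.deg[i];
    if (k < 2) continue;
    const uint64_t* ri = g.row(i);
    int tri2 = 0; // twice the triangle count at i
    for (int w = 0; w < W; ++w) {
      uint64_t x = ri[w];
      while (x) {
        int j = (w << 6) + ctz64(x);
        x &= x - 1;
        const uint64_t* rj = g.row(j);
        for (int v = 0; v < W; ++v) tri2 += popcnt64(ri[v] & rj[v]);
      }
    }
    total += (double)tri2 / ((double)k * (k - 1));
  }
  return total / n;
}

// local efficiency: mean over nodes of the efficiency of the neighbour-
// induced subgraph; nodes with < 2 neighbours contribute 0.
static double local_eff_bits(const BitGraph& g) {
  int n = g.n, W = g.W;
  std::vector<uint64_t> vis(W), fr(W), nx(W);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = g.deg[i];
    if (k < 2) continue;
    const uint64_t* S = g.row(i);
    double inv = 0, ds = 0, rc = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t x = S[w];
      while (x) {
        int s = (w << 6) + ctz64(x);
        x &= x - 1;
        bfs_sums(g, s, S, vis.data(), fr.data(), nx.data(), inv, ds, rc);
      }
    }
    total += inv / ((double)k * (k - 1));
  }
  return total / n;
}

// [[Rcpp::export]]
double cpp_global_efficiency(IntegerMatrix adj) {
  BitGraph g; bitgraph_from_adj(adj, g);
  return global_eff_bits(g);
}

// [[Rcpp::export]]
double cpp_local_efficiency(IntegerMatrix adj) {
  BitGraph g; bitgraph_from_adj(adj, g);
  return local_eff_bits(g);
}

// [[Rcpp::export]]
double cpp_clustering(IntegerMatrix adj) {
  BitGraph g; bitgraph_from_adj(adj, g);
  return clustering_bits(g);
}

// Returns c(sum of shortest-path lengths over reachable ordered pairs,
//           number of reachable ordered pairs).
// [[Rcpp::export]]
NumericVector cpp_path_length(IntegerMatrix adj) {
  BitGraph g; bitgraph_from_adj(adj, g);
  double ds, rc;
  path_sums_bits(g, ds, rc);
  return NumericVector::create(ds, rc);
}

// All-pairs BFS distance matrix (-1 for unreachable off-diagonal pairs).
// [[Rcpp::export]]
IntegerMatrix cpp_distance_matrix(IntegerMatrix adj) {
  int n = adj.nrow();
  BitGraph g; bitgraph_from_adj(adj, g);
  IntegerMatrix out(n, n);
  std::fill(out.begin(), out.end(), -1);
  std::vector<uint64_t> vis(g.W), fr(g.W), nx(g.W);
  for (int src = 0; src < n; ++src) {
    // explicit level-by-level BFS to record distances
    for (int w = 0; w < g.W; ++w) { vis[w] = 0; fr[w] = 0; }
    vis[src >> 6] = fr[src >> 6] = 1ULL << (src & 63);
    out(src, src) = 0;
    int d = 0;
    while (true) {
      for (int w = 0; w < g.W; ++w) nx[w] = 0;
      for (int w = 0; w < g.W; ++w) {
        uint64_t x = fr[w];
        while (x) {
          int u = (w << 6) + ctz64(x);
          x &= x - 1;
          const uint64_t* r = g.row(u);
          for (int v = 0; v < g.W; ++v) nx[v] |= r[v];
        }
      }
      ++d;
      int c = 0;
      for (int w = 0; w < g.W; ++w) {
        nx[w] &= ~vis[w];
        vis[w] |= nx[w];
        c += popcnt64(nx[w]);
        uint64_t x = nx[w];
        while (x) {
          out((w << 6) + ctz64(x), src) = d;
          x &= x - 1;
        }
      }
      if (c == 0) break;
      std::swap(fr, nx);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Louvain community detection (Newman-Girvan modularity, resolution 1)
// ---------------------------------------------------------------------------
struct WGraph {
  int n;
  std::vector<std::vector<std::pair<int, double>>> nb; // excludes self loops
  std::vector<double> selfw;  // self-loop weight
  std::vector<double> k;      // node strength (self loop counted twice)
  double m2;                  // total strength = 2m
};

static void wgraph_from_bits(const BitGraph& bg, WGraph& g) {
  int n = bg.n;
  g.n = n;
  g.nb.assign(n, {});
  g.selfw.assign(n, 0.0);
  g.k.assign(n, 0.0);
  g.m2 = 0.0;
  for (int i = 0; i < n; ++i) {
    const uint64_t* r = bg.row(i);
    g.nb[i].reserve(bg.deg[i]);
    for (int w = 0; w < bg.W; ++w) {
      uint64_t x = r[w];
      while (x) {
        int j = (w << 6) + ctz64(x);
        x &= x - 1;
        g.nb[i].push_back({j, 1.0});
      }
    }
    g.k[i] = bg.deg[i];
    g.m2 += g.k[i];
  }
}

// One level of local moving; returns true if any node changed community.
static bool one_level(const WGraph& g, std::vector<int>& comm, RngState& rng) {
  int n = g.n;
  std::vector<double> tot(n, 0.0);
  comm.assign(n, 0);
  for (int i = 0; i < n; ++i) { comm[i] = i; tot[i] = g.k[i]; }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  rng.shuffle(order);
  std::vector<double> w2c(n, 0.0);
  std::vector<char> seen(n, 0);
  std::vector<int> touched;
  bool improved = false, moved = true;
  while (moved) {
    moved = false;
    for (int idx = 0; idx < n; ++idx) {
      int u = order[idx];
      touched.clear();
      for (auto& e : g.nb[u]) {
        int c = comm[e.first];
        if (!seen[c]) { seen[c] = 1; touched.push_back(c); w2c[c] = 0.0; }
        w2c[c] += e.second;
      }
      int cu = comm[u];
      tot[cu] -= g.k[u];
      double wcu = seen[cu] ? w2c[cu] : 0.0;
      double best_gain = wcu - tot[cu] * g.k[u] / g.m2;
      int best = cu;
      for (int c : touched) {
        if (c == cu) continue;
        double gain = w2c[c] - tot[c] * g.k[u] / g.m2;
        if (gain > best_gain + 1e-12) { best_gain = gain; best = c; }
      }
      tot[best] += g.k[u];
      comm[u] = best;
      if (best != cu) { moved = true; improved = true; }
      for (int c : touched) seen[c] = 0;
    }
  }
  return improved;
}

// Aggregate graph by communities (renumbered by first appearance).
static void aggregate(const WGraph& g, const std::vector<int>& comm,
                      WGraph& out, std::vector<int>& relabel) {
  int n = g.n;
  relabel.assign(n, -1);
  int nc = 0;
  for (int i = 0; i < n; ++i)
    if (relabel[comm[i]] < 0) relabel[comm[i]] = nc++;
  out.n = nc;
  out.nb.assign(nc, {});
  out.selfw.assign(nc, 0.0);
  out.k.assign(nc, 0.0);
  out.m2 = g.m2;
  std::vector<std::vector<double>> w(nc, std::vector<double>(nc, 0.0));
  for (int u = 0; u < n; ++u) {
    int cu = relabel[comm[u]];
    out.selfw[cu] += g.selfw[u];
    for (auto& e : g.nb[u]) {
      int cv = relabel[comm[e.first]];
      if (cv == cu) out.selfw[cu] += e.second / 2.0; // each edge seen twice
      else w[cu][cv] += e.second;
    }
  }
  for (int a = 0; a < nc; ++a) {
    out.k[a] = 2.0 * out.selfw[a];
    for (int b = 0; b < nc; ++b)
      if (b != a && w[a][b] > 0.0) {
        out.nb[a].push_back({b, w[a][b]});
        out.k[a] += w[a][b];
      }
  }
}

// Newman-Girvan Q of a flat membership on the base (binary) graph.
static double modularity_q(const WGraph& base, const std::vector<int>& memb) {
  int n = base.n;
  int nc = 0;
  for (int i = 0; i < n; ++i) nc = std::max(nc, memb[i] + 1);
  std::vector<double> e(nc, 0.0), d(nc, 0.0);
  double m = base.m2 / 2.0;
  if (m == 0.0) return NA_REAL;
  for (int i = 0; i < n; ++i) {
    d[memb[i]] += base.k[i];
    for (auto& ed : base.nb[i])
      if (memb[ed.first] == memb[i]) e[memb[i]] += ed.second / 2.0;
  }
  double q = 0.0;
  for (int c = 0; c < nc; ++c)
    q += e[c] / m - (d[c] / (2.0 * m)) * (d[c] / (2.0 * m));
  return q;
}

static void louvain_once(const WGraph& base, RngState& rng,
                         std::vector<int>& flat) {
  int n0 = base.n;
  flat.resize(n0);
  for (int i = 0; i < n0; ++i) flat[i] = i;
  std::vector<int> comm, relabel;
  const WGraph* cur = &base;
  WGraph buf_a, buf_b;
  bool use_a = true;
  while (true) {
    bool improved = one_level(*cur, comm, rng);
    WGraph& nxt = use_a ? buf_a : buf_b;
    aggregate(*cur, comm, nxt, relabel);
    for (int i = 0; i < n0; ++i) flat[i] = relabel[comm[flat[i]]];
    if (!improved || nxt.n == cur->n) break;
    cur = &nxt;
    use_a = !use_a;
  }
}

static double louvain_best(const WGraph& base, int n_restarts, RngState& rng,
                           std::vector<int>* best_memb) {
  double best_q = -1e18;
  std::vector<int> flat;
  for (int r = 0; r < n_restarts; ++r) {
    louvain_once(base, rng, flat);
    double q = modularity_q(base, flat);
    if (q > best_q) {
      best_q = q;
      if (best_memb) *best_memb = flat;
    }
  }
  if (best_q < 0.0) {
    best_q = 0.0;
    if (best_memb) best_memb->assign(base.n, 0);
  }
  return best_q;
}

// Best-of-restarts Louvain; returns list(Q, membership 1-based, n_modules).
// Falls back to the one-module partition (Q = 0) if every restart yields a
// negative Q.
// [[Rcpp::export]]
List cpp_louvain(IntegerMatrix adj, int n_restarts, int seed) {
  int n = adj.nrow();
  BitGraph bg; bitgraph_from_adj(adj, bg);
  WGraph base; wgraph_from_bits(bg, base);
  RngState rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<int> best(n, 0);
  double best_q = louvain_best(base, n_restarts, rng, &best);
  // renumber modules by first appearance, 1-based
  std::vector<int> map(n, -1);
  int nc = 0;
  IntegerVector memb(n);
  for (int i = 0; i < n; ++i) {
    if (map[best[i]] < 0) map[best[i]] = nc++;
    memb[i] = map[best[i]] + 1;
  }
  return List::create(_["Q"] = best_q, _["membership"] = memb,
                      _["n_modules"] = nc);
}

// Q of a given membership (1-based integer vector).
// [[Rcpp::export]]
double cpp_modularity(IntegerMatrix adj, IntegerVector membership) {
  BitGraph bg; bitgraph_from_adj(adj, bg);
  WGraph base; wgraph_from_bits(bg, base);
  int n = adj.nrow();
  std::vector<int> memb(n);
  for (int i = 0; i < n; ++i) memb[i] = membership[i] - 1;
  return modularity_q(base, memb);
}

// ---------------------------------------------------------------------------
// Degree-preserving rewiring (Maslov-Sneppen double-edge swaps)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerMatrix adj, int attempts, int seed) {
  int n = adj.nrow();
  IntegerMatrix a = clone(adj);
  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j) != 0) edges.push_back({i, j});
  int m = (int)edges.size();
  if (m < 2) return a;
  RngState rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);
  for (int t = 0; t < attempts; ++t) {
    int e1 = rng.below(m), e2 = rng.below(m);
    if (e1 == e2) continue;
    int a1 = edges[e1].first, b1 = edges[e1].second;
    int a2 = edges[e2].first, b2 = edges[e2].second;
    if (rng.below(2)) std::swap(a2, b2);
    // proposed replacement edges: (a1,b2) and (a2,b1)
    if (a1 == b2 || a2 == b1) continue;
    if (a1 == a2 || b1 == b2) continue;
    if (a(a1, b2) != 0 || a(a2, b1) != 0) continue;
    a(a1, b1) = a(b1, a1) = 0;
    a(a2, b2) = a(b2, a2) = 0;
    a(a1, b2) = a(b2, a1) = 1;
    a(a2, b1) = a(b1, a2) = 1;
    edges[e1] = {std::min(a1, b2), std::max(a1, b2)};
    edges[e2] = {std::min(a2, b1), std::max(a2, b1)};
  }
  return a;
}

// ---------------------------------------------------------------------------
// Batched objective evaluation for the evolutionary loop.
// genomes: L x P 0/1 matrix, column = one network's upper triangle.
// ii, jj: 1-based node indices of each genome position.
// model: 1 = dual (1-Eg), 2 = tri_eloc, 3 = tri_q.
// Edgeless genomes get F_e = 1 (worst) so evolution can proceed.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_eval_genomes(IntegerMatrix genomes, int n,
                               IntegerVector ii, IntegerVector jj,
                               int model, double w,
                               int louvain_restarts, int seed) {
  int L = genomes.nrow(), P = genomes.ncol();
  NumericVector fe(P);
  RngState rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 13ULL);
  BitGraph g;
  WGraph base;
  for (int p = 0; p < P; ++p) {
    g.init(n);
    int m = 0;
    for (int l = 0; l < L; ++l)
      if (genomes(l, p) != 0) {
        g.add_edge(ii[l] - 1, jj[l] - 1);
        ++m;
      }
    if (m == 0) { fe[p] = 1.0; continue; }
    double eg = global_eff_bits(g);
    if (model == 1) {
      fe[p] = 1.0 - eg;
    } else if (model == 2) {
      double eloc = local_eff_bits(g);
      fe[p] = w * (1.0 - eg) + (1.0 - w) * (1.0 - eloc);
    } else {
      wgraph_from_bits(g, base);
      double best_q = louvain_best(base, louvain_restarts, rng, nullptr);
      fe[p] = w * (1.0 - eg) + (1.0 - w) * (1.0 - best_q);
    }
  }
  return fe;
}
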