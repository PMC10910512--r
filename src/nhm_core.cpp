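// Core graph machinery for network Hamiltonian models: exact sufficient
// statistics, O(local) change statistics for edge toggles, the
// Metropolis-Hastings edge-toggle sampler, and the periodic fibril-template
// matcher. Node indices are 0-based throughout; graphs are simple and
// undirected.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <random>
#include <cstdint>
using namespace Rcpp;

// Statistic codes (keep in sync with .stat_codes in R/netstats.R):
// 0 edges, 1 twostar, 2 nsp1, 3 nsp2, 4 esp0, 5 esp1,
// 6 cycle3, 7 cycle5, 8 cycle6, 9 cycle7
enum StatCode {
  ST_EDGES = 0, ST_TWOSTAR = 1, ST_NSP1 = 2, ST_NSP2 = 3,
  ST_ESP0 = 4, ST_ESP1 = 5, ST_C3 = 6, ST_C5 = 7, ST_C6 = 8, ST_C7 = 9
};

namespace {

struct Graph {
  int n;
  std::vector<std::vector<int>> adj;   // neighbor lists, kept sorted
  std::vector<uint8_t> amat;           // flat n*n adjacency indicator
  long nEdges;
  // edge vector + index for O(1) uniform edge sampling (canonical u < v)
  std::vector<std::pair<int,int>> edgeVec;
  std::vector<int> eidx;               // position of edge (u,v), u < v, in edgeVec

  explicit Graph(int n_) : n(n_), adj(n_), amat((size_t)n_ * n_, 0), nEdges(0),
                           eidx((size_t)n_ * n_, -1) {}

  bool has(int u, int v) const { return amat[(size_t)u * n + v] != 0; }

  void addEdge(int u, int v) {
    adj[u].insert(std::lower_bound(adj[u].begin(), adj[u].end(), v), v);
    adj[v].insert(std::lower_bound(adj[v].begin(), adj[v].end(), u), u);
    amat[(size_t)u * n + v] = amat[(size_t)v * n + u] = 1;
    int a = std::min(u, v), b = std::max(u, v);
    eidx[(size_t)a * n + b] = (int)edgeVec.size();
    edgeVec.push_back({a, b});
    ++nEdges;
  }

  void removeEdge(int u, int v) {
    adj[u].erase(std::lower_bound(adj[u].begin(), adj[u].end(), v));
    adj[v].erase(std::lower_bound(adj[v].begin(), adj[v].end(), u));
    amat[(size_t)u * n + v] = amat[(size_t)v * n + u] = 0;
    int a = std::min(u, v), b = std::max(u, v);
    int pos = eidx[(size_t)a * n + b];
    std::pair<int,int> last = edgeVec.back();
    edgeVec[pos] = last;
    eidx[(size_t)last.first * n + last.second] = pos;
    edgeVec.pop_back();
    eidx[(size_t)a * n + b] = -1;
    --nEdges;
  }

  int deg(int v) const { return (int)adj[v].size(); }

  // |N(a) ∩ N(b)|, iterating over the smaller list
  int commonNeighbors(int a, int b) const {
    const std::vector<int>& sa = adj[a].size() <= adj[b].size() ? adj[a] : adj[b];
    int other = (&sa == &adj[a]) ? b : a;
    int c = 0;
    for (int w : sa) if (has(w, other)) ++c;
    return c;
  }
};

Graph buildGraph(int n, const IntegerMatrix& edges) {
  Graph g(n);
  for (int i = 0; i < edges.nrow(); ++i) {
    int u = edges(i, 0), v = edges(i, 1);
    if (u < 0 || v < 0 || u >= n || v >= n)
      stop("edge endpoint out of range [0, n)");
    if (u == v) stop("self-loops are not allowed");
    if (g.has(u, v)) stop("duplicate edge in edge list");
    g.addEdge(u, v);
  }
  return g;
}

// ---- exact counts ---------------------------------------------------------

// Simple cycles of length exactly k, each counted once. Enumerates paths
// anchored at their minimum node; each cycle is hit twice (two directions).
struct CycleCounter {
  const Graph& g;
  int k, v0;
  long count;
  std::vector<uint8_t> onPath;
  CycleCounter(const Graph& g_, int k_) : g(g_), k(k_), count(0), onPath(g_.n, 0) {}

  void dfs(int x, int depth) {
    if (depth == k - 1) {
      if (g.has(x, v0)) ++count;
      return;
    }
    for (int w : g.adj[x]) {
      if (w <= v0 || onPath[w]) continue;
      onPath[w] = 1;
      dfs(w, depth + 1);
      onPath[w] = 0;
    }
  }

  long run() {
    for (v0 = 0; v0 < g.n; ++v0) {
      dfs(v0, 0);
    }
    return count / 2;
  }
};

double countStat(const Graph& g, int code) {
  switch (code) {
  case ST_EDGES:
    return (double)g.nEdges;
  case ST_TWOSTAR: {
    double s = 0;
    for (int v = 0; v < g.n; ++v) {
      double d = g.deg(v);
      s += d * (d - 1) / 2.0;
    }
    return s;
  }
  case ST_NSP1: case ST_NSP2: case ST_ESP0: case ST_ESP1: {
    int wantK = (code == ST_NSP1 || code == ST_ESP1) ? 1 : (code == ST_NSP2 ? 2 : 0);
    bool wantAdj = (code == ST_ESP0 || code == ST_ESP1);
    long c = 0;
    for (int i = 0; i < g.n; ++i)
      for (int j = i + 1; j < g.n; ++j) {
        if (g.has(i, j) != wantAdj) continue;
        if (g.commonNeighbors(i, j) == wantK) ++c;
      }
    return (double)c;
  }
  case ST_C3: case ST_C5: case ST_C6: case ST_C7: {
    int k = (code == ST_C3) ? 3 : (code == ST_C5) ? 5 : (code == ST_C6) ? 6 : 7;
    CycleCounter cc(g, k);
    return (double)cc.run();
  }
  default:
    stop("unknown statistic code");
  }
  return 0; // unreachable
}

// ---- change statistics ----------------------------------------------------

// Simple paths u -> v of length exactly `len` edges (intermediates distinct,
// excluding u and v). Any edge u-v itself can only appear as a length-1 path,
// so counts for len >= 2 are unaffected by the toggled dyad's own edge.
struct PathCounter {
  const Graph& g;
  int u, v, maxLen;
  std::vector<long> hits;   // hits[L] = #paths of length L
  std::vector<uint8_t> onPath;
  std::vector<int> distV;   // BFS distance to v; prunes hopeless branches
  PathCounter(const Graph& g_, int u_, int v_, int maxLen_)
    : g(g_), u(u_), v(v_), maxLen(maxLen_), hits(maxLen_ + 1, 0),
      onPath(g_.n, 0), distV(g_.n, maxLen_ + 1) {}

  void dfs(int x, int depth) {
    for (int w : g.adj[x]) {
      if (w == v) {
        if (depth + 1 >= 2) ++hits[depth + 1];
        continue;
      }
      if (w == u || onPath[w]) continue;
      if (depth + 1 + distV[w] <= maxLen) {
        onPath[w] = 1;
        dfs(w, depth + 1);
        onPath[w] = 0;
      }
    }
  }

  void run() {
    // breadth-first distances to v (a lower bound for the remaining path
    // length even when some nodes are already on the path)
    std::vector<int> queue;
    distV[v] = 0;
    queue.push_back(v);
    for (size_t qi = 0; qi < queue.size(); ++qi) {
      int x = queue[qi];
      if (distV[x] >= maxLen) break;
      for (int w : g.adj[x])
        if (distV[w] > distV[x] + 1) {
          distV[w] = distV[x] + 1;
          queue.push_back(w);
        }
    }
    dfs(u, 0);
  }
};

// Change in all requested statistics when dyad (u,v) is toggled in g.
// `adding` must reflect !g.has(u,v).
void changeStats(const Graph& g, int u, int v, bool adding,
                 const IntegerVector& codes, double* out) {
  int nc = codes.size();
  double sgn = adding ? 1.0 : -1.0;

  bool needSP = false;
  int maxPathLen = 0;
  for (int i = 0; i < nc; ++i) {
    int c = codes[i];
    if (c == ST_NSP1 || c == ST_NSP2 || c == ST_ESP0 || c == ST_ESP1) needSP = true;
    if (c == ST_C3) maxPathLen = std::max(maxPathLen, 2);
    if (c == ST_C5) maxPathLen = std::max(maxPathLen, 4);
    if (c == ST_C6) maxPathLen = std::max(maxPathLen, 5);
    if (c == ST_C7) maxPathLen = std::max(maxPathLen, 6);
  }

  // shared-partner shifts accumulated per (category, k) for tracked k
  double dNsp1 = 0, dNsp2 = 0, dEsp0 = 0, dEsp1 = 0;
  if (needSP) {
    auto shift = [&](bool adjPair, int cOld, int cNew) {
      if (adjPair) {
        if (cOld == 0) --dEsp0; else if (cOld == 1) --dEsp1;
        if (cNew == 0) ++dEsp0; else if (cNew == 1) ++dEsp1;
      } else {
        if (cOld == 1) --dNsp1; else if (cOld == 2) --dNsp2;
        if (cNew == 1) ++dNsp1; else if (cNew == 2) ++dNsp2;
      }
    };
    int cuv = g.commonNeighbors(u, v);
    // the dyad itself changes category (its own partner count is unchanged)
    if (adding) {
      if (cuv == 1) --dNsp1; else if (cuv == 2) --dNsp2;
      if (cuv == 0) ++dEsp0; else if (cuv == 1) ++dEsp1;
    } else {
      if (cuv == 0) --dEsp0; else if (cuv == 1) --dEsp1;
      if (cuv == 1) ++dNsp1; else if (cuv == 2) ++dNsp2;
    }
    // every neighbor w of u gains/loses u as a shared partner with v, and
    // symmetrically for neighbors of v
    int dShift = adding ? +1 : -1;
    for (int w : g.adj[u]) {
      if (w == v) continue;
      int cOld = g.commonNeighbors(w, v);
      shift(g.has(w, v), cOld, cOld + dShift);
    }
    for (int w : g.adj[v]) {
      if (w == u) continue;
      int cOld = g.commonNeighbors(w, u);
      shift(g.has(w, u), cOld, cOld + dShift);
    }
  }

  long p2 = 0, p4 = 0, p5 = 0, p6 = 0;
  if (maxPathLen > 0) {
    if (maxPathLen == 2) {
      p2 = g.commonNeighbors(u, v);
    } else {
      PathCounter pc(g, u, v, maxPathLen);
      pc.run();
      p2 = pc.hits[2];
      if (maxPathLen >= 4) p4 = pc.hits[4];
      if (maxPathLen >= 5) p5 = pc.hits[5];
      if (maxPathLen >= 6) p6 = pc.hits[6];
    }
  }

  for (int i = 0; i < nc; ++i) {
    double d = 0;
    switch (codes[i]) {
    case ST_EDGES: d = sgn; break;
    case ST_TWOSTAR: {
      int du = g.deg(u) - (adding ? 0 : 1);
      int dv = g.deg(v) - (adding ? 0 : 1);
      d = sgn * (du + dv);
      break;
    }
    case ST_NSP1: d = dNsp1; break;
    case ST_NSP2: d = dNsp2; break;
    case ST_ESP0: d = dEsp0; break;
    case ST_ESP1: d = dEsp1; break;
    case ST_C3: d = sgn * p2; break;
    case ST_C5: d = sgn * p4; break;
    case ST_C6: d = sgn * p5; break;
    case ST_C7: d = sgn * p6; break;
    default: stop("unknown statistic code");
    }
    out[i] = d;
  }
}

// Deterministic 32-bit RNG helpers (avoid std::*_distribution, whose output
// is implementation-defined).
inline uint32_t randBelow(std::mt19937& rng, uint32_t range) {
  uint32_t limit = UINT32_MAX - (UINT32_MAX % range);
  uint32_t r;
  do { r = rng(); } while (r >= limit);
  return r % range;
}

inline double randUnit(std::mt19937& rng) {
  return (rng() + 0.5) * (1.0 / 4294967296.0);
}

IntegerMatrix edgesOf(const Graph& g) {
  IntegerMatrix out(g.nEdges, 2);
  int k = 0;
  for (int u = 0; u < g.n; ++u)
    for (int w : g.adj[u])
      if (w > u) { out(k, 0) = u; out(k, 1) = w; ++k; }
  return out;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_compute_stats(int n, IntegerMatrix edges, IntegerVector codes) {
  Graph g = buildGraph(n, edges);
  NumericVector out(codes.size());
  for (int i = 0; i < codes.size(); ++i) out[i] = countStat(g, codes[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_change_stats(int n, IntegerMatrix edges, int u, int v,
                               IntegerVector codes) {
  Graph g = buildGraph(n, edges);
  if (u == v) stop("self-loop dyad");
  NumericVector out(codes.size());
  changeStats(g, u, v, !g.has(u, v), codes, REAL(out));
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(int n, IntegerMatrix initEdges, IntegerVector codes,
                  NumericVector theta, double burnin, int seed,
                  double maxEdgesGuard, double swapFraction) {
  if (theta.size() != codes.size()) stop("theta/codes length mismatch");
  if (swapFraction < 0 || swapFraction > 1)
    stop("swapFraction must lie in [0, 1]");
  Graph g = buildGraph(n, initEdges);

  int nc = codes.size();
  NumericVector stats(nc);
  for (int i = 0; i < nc; ++i) stats[i] = countStat(g, codes[i]);

  std::mt19937 rng((uint32_t)seed);
  std::vector<double> delta(nc), total(nc);
  long accepted = 0;
  bool degenerate = false;
  double proposed = 0;

  for (double step = 0; step < burnin; ++step) {
    ++proposed;
    bool doSwap = swapFraction > 0 && randUnit(rng) < swapFraction;

    if (doSwap) {
      // degree-preserving double-edge swap: (u-v, x-y) -> (u-x, v-y) or
      // (u-y, v-x). Both states have the same edge count, so the uniform
      // edge-pair selection probabilities cancel and the kernel is
      // symmetric; invalid proposals (shared nodes, target edge present)
      // are rejected outright.
      if (g.nEdges < 2) continue;
      uint32_t e1 = randBelow(rng, (uint32_t)g.nEdges);
      uint32_t e2 = randBelow(rng, (uint32_t)(g.nEdges - 1));
      if (e2 >= e1) ++e2;
      int u = g.edgeVec[e1].first, v = g.edgeVec[e1].second;
      int x = g.edgeVec[e2].first, y = g.edgeVec[e2].second;
      if (randUnit(rng) < 0.5) std::swap(x, y);
      // proposed new edges: u-x and v-y
      if (u == x || u == y || v == x || v == y) continue;
      if (g.has(u, x) || g.has(v, y)) continue;

      std::fill(total.begin(), total.end(), 0.0);
      const int ops[4][3] = {{u, v, 0}, {x, y, 0}, {u, x, 1}, {v, y, 1}};
      int applied = 0;
      for (int k = 0; k < 4; ++k) {
        changeStats(g, ops[k][0], ops[k][1], ops[k][2] == 1, codes,
                    delta.data());
        for (int i = 0; i < nc; ++i) total[i] += delta[i];
        if (ops[k][2]) g.addEdge(ops[k][0], ops[k][1]);
        else g.removeEdge(ops[k][0], ops[k][1]);
        ++applied;
      }
      double lr = 0;
      for (int i = 0; i < nc; ++i) lr += theta[i] * total[i];
      if (lr >= 0 || randUnit(rng) < std::exp(lr)) {
        for (int i = 0; i < nc; ++i) stats[i] += total[i];
        ++accepted;
      } else {
        for (int k = applied - 1; k >= 0; --k) {  // revert
          if (ops[k][2]) g.removeEdge(ops[k][0], ops[k][1]);
          else g.addEdge(ops[k][0], ops[k][1]);
        }
      }
    } else {
      int u = (int)randBelow(rng, (uint32_t)n);
      int v = (int)randBelow(rng, (uint32_t)(n - 1));
      if (v >= u) ++v;                     // uniform unordered dyad
      bool adding = !g.has(u, v);
      changeStats(g, u, v, adding, codes, delta.data());
      double lr = 0;
      for (int i = 0; i < nc; ++i) lr += theta[i] * delta[i];
      if (lr >= 0 || randUnit(rng) < std::exp(lr)) {
        if (adding) g.addEdge(u, v); else g.removeEdge(u, v);
        for (int i = 0; i < nc; ++i) stats[i] += delta[i];
        ++accepted;
        if (g.nEdges > maxEdgesGuard) { degenerate = true; break; }
      }
    }
  }

  return List::create(
    _["edges"] = edgesOf(g),
    _["stats"] = stats,
    _["accepted"] = (double)accepted,
    _["proposed"] = proposed,
    _["degenerate"] = degenerate);
}

// ---- fibril template matching --------------------------------------------
//
// A template with S strands is matched unit by unit: a unit is an S-tuple of
// distinct nodes realizing the intra-unit rules (axial offset 0); consecutive
// units must realize the inter-unit rules (axial offset 1). A node is
// fibrillar when (a) it sits at an interior (non-terminal) position of an
// embedded chain of >= minUnits units with all template edges present,
// (b) hence its complete interior neighborhood is present, and (c) its degree
// equals the template's interior degree for its strand, so it carries no
// edges outside the matched pattern.

namespace {

struct TemplateDef {
  int S;
  std::vector<std::pair<int,int>> intra;  // (a,b) offset-0 rules
  std::vector<std::pair<int,int>> inter;  // (a,b) offset-1 rules: (unit i, a) - (unit i+1, b)
  std::vector<int> intDeg;                // interior degree per strand
  int minUnits;
};

struct Matcher {
  const Graph& g;
  const TemplateDef& T;
  std::vector<uint8_t> used;     // nodes committed to the current chain
  Matcher(const Graph& g_, const TemplateDef& T_) : g(g_), T(T_), used(g_.n, 0) {}

  // enumerate unit tuples subject to intra rules; `fixStrand`>=0 pins a node.
  // yield() returns true to stop the enumeration (witness found).
  template <typename F>
  bool enumUnits(int fixStrand, int fixNode,
                 const std::vector<std::vector<int>>* anchorCands,
                 F&& yield) {
    std::vector<int> tup(T.S, -1);
    return fillStrand(0, fixStrand, fixNode, anchorCands, tup, yield);
  }

  template <typename F>
  bool fillStrand(int nAssigned, int fixStrand, int fixNode,
                  const std::vector<std::vector<int>>* anchorCands,
                  std::vector<int>& tup, F&& yield) {
    if (nAssigned == T.S) return yield(tup);

    // pick the next strand: the pinned one first, then strands reachable
    // from an assigned intra partner, then anchored strands, then any
    int s = -1;
    if (fixStrand >= 0 && tup[fixStrand] < 0) {
      s = fixStrand;
    } else {
      for (int j = 0; j < T.S && s < 0; ++j) {
        if (tup[j] >= 0) continue;
        for (auto& r : T.intra) {
          int o = (r.first == j) ? r.second : (r.second == j ? r.first : -1);
          if (o >= 0 && tup[o] >= 0) { s = j; break; }
        }
      }
      if (s < 0 && anchorCands)
        for (int j = 0; j < T.S && s < 0; ++j)
          if (tup[j] < 0 && !(*anchorCands)[j].empty()) s = j;
      if (s < 0)
        for (int j = 0; j < T.S && s < 0; ++j)
          if (tup[j] < 0) s = j;
    }

    auto ok = [&](int cand) {
      if (cand < 0) return false;
      // degree strictness applies only to the focal node (checked by the
      // caller); other segment nodes may carry edges outside the pattern
      if (used[cand]) return false;
      for (int j = 0; j < T.S; ++j)
        if (tup[j] == cand) return false;
      // all intra rules touching s with already-assigned strands
      for (auto& r : T.intra) {
        int o = (r.first == s) ? r.second : (r.second == s ? r.first : -1);
        if (o >= 0 && tup[o] >= 0 && !g.has(cand, tup[o])) return false;
      }
      // inter anchor constraints (when extending a chain)
      if (anchorCands && !(*anchorCands)[s].empty()) {
        for (int a : (*anchorCands)[s]) if (!g.has(cand, a)) return false;
      }
      return true;
    };

    if (s == fixStrand) {
      if (!ok(fixNode)) return false;
      tup[s] = fixNode;
      if (fillStrand(nAssigned + 1, fixStrand, fixNode, anchorCands, tup, yield))
        return true;
      tup[s] = -1;
      return false;
    }

    // candidate source: neighbors of an intra-assigned partner, else of an
    // inter anchor, else every node (S==1 chains are anchored by fix/inter)
    const std::vector<int>* cands = nullptr;
    for (auto& r : T.intra) {
      int o = (r.first == s) ? r.second : (r.second == s ? r.first : -1);
      if (o >= 0 && tup[o] >= 0) { cands = &g.adj[tup[o]]; break; }
    }
    if (!cands && anchorCands && !(*anchorCands)[s].empty())
      cands = &g.adj[(*anchorCands)[s][0]];

    if (cands) {
      for (int c : *cands) {
        if (!ok(c)) continue;
        tup[s] = c;
        if (fillStrand(nAssigned + 1, fixStrand, fixNode, anchorCands, tup, yield))
          return true;
        tup[s] = -1;
      }
    } else {
      for (int c = 0; c < g.n; ++c) {
        if (!ok(c)) continue;
        tup[s] = c;
        if (fillStrand(nAssigned + 1, fixStrand, fixNode, anchorCands, tup, yield))
          return true;
        tup[s] = -1;
      }
    }
    return false;
  }

  // extend the chain from `cur` by `depth` more units; dir=+1 extends right
  // (inter rules run cur->next), dir=-1 extends left (rules run prev->cur)
  bool extend(const std::vector<int>& cur, int depth, int dir) {
    if (depth == 0) return true;
    // anchors: for each strand of the new unit, the nodes it must touch
    std::vector<std::vector<int>> anchors(T.S);
    for (auto& r : T.inter) {
      if (dir > 0) anchors[r.second].push_back(cur[r.first]);
      else         anchors[r.first].push_back(cur[r.second]);
    }
    return enumUnits(-1, -1, &anchors, [&](std::vector<int>& nxt) {
      for (int x : nxt) used[x] = 1;
      bool found = extend(nxt, depth - 1, dir);
      for (int x : nxt) used[x] = 0;
      return found;
    });
  }

  // is node v fibrillar at strand s?
  bool witness(int v, int s) {
    return enumUnits(s, v, nullptr, [&](std::vector<int>& mid) {
      for (int x : mid) used[x] = 1;
      bool found = false;
      // need left run l>=1 and right run r>=1 with l+1+r >= minUnits
      int need = std::max(1, T.minUnits - 2);
      for (int l = 1; l <= need && !found; ++l) {
        int r = std::max(1, T.minUnits - 1 - l);
        // extend left l units, marking them used, then right r units
        found = extendBoth(mid, l, r);
        if (l >= need) break;
      }
      for (int x : mid) used[x] = 0;
      return found;
    });
  }

  bool extendBoth(const std::vector<int>& mid, int l, int r) {
    // left extension with nested right extension from mid
    std::function<bool(const std::vector<int>&, int)> goLeft =
      [&](const std::vector<int>& cur, int depth) -> bool {
        if (depth == 0) return extend(mid, r, +1);
        std::vector<std::vector<int>> anchors(T.S);
        for (auto& rr : T.inter) anchors[rr.first].push_back(cur[rr.second]);
        return enumUnits(-1, -1, &anchors, [&](std::vector<int>& prv) {
          for (int x : prv) used[x] = 1;
          bool found = goLeft(prv, depth - 1);
          for (int x : prv) used[x] = 0;
          return found;
        });
      };
    return goLeft(mid, l);
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_fibril_nodes(int n, IntegerMatrix edges, int strands,
                               IntegerMatrix intra, IntegerMatrix inter,
                               IntegerVector intDeg, int minUnits) {
  Graph g = buildGraph(n, edges);
  TemplateDef T;
  T.S = strands;
  T.minUnits = minUnits;
  for (int i = 0; i < intra.nrow(); ++i)
    T.intra.push_back({intra(i, 0), intra(i, 1)});
  for (int i = 0; i < inter.nrow(); ++i)
    T.inter.push_back({inter(i, 0), inter(i, 1)});
  T.intDeg = std::vector<int>(intDeg.begin(), intDeg.end());

  std::vector<int> hits;
  Matcher m(g, T);
  for (int v = 0; v < n; ++v) {
    bool fib = false;
    for (int s = 0; s < strands && !fib; ++s) {
      if (g.deg(v) != T.intDeg[s]) continue;
      fib = m.witness(v, s);
    }
    if (fib) hits.push_back(v);
  }
  return wrap(hits);
}
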