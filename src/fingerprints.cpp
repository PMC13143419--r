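// Core fingerprint machinery.
//
// All substructure identifiers are 64-bit FNV-1a hashes of canonical,
// documented ASCII strings (see hash_layouts in R/fingerprints.R).  Keys are
// passed to R as 16-char lowercase hex strings because R has no native
// unsigned 64-bit integer type.
//
// Bond order codes on the R side: 1 = single, 2 = double, 4 = aromatic.
// For fractional bond-order sums aromatic counts 1.5.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <map>
#include <set>
#include <unordered_set>
#include <unordered_map>
#include <queue>
#include <algorithm>
#include <functional>
#include <array>

using namespace Rcpp;

static const uint64_t FNV_OFFSET = 1469598103934665603ULL;
static const uint64_t FNV_PRIME = 1099511628211ULL;

static uint64_t fnv1a(const std::string& s) {
  uint64_t h = FNV_OFFSET;
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= FNV_PRIME;
  }
  return h;
}

static std::string hex64(uint64_t x) {
  static const char* digits = "0123456789abcdef";
  std::string out(16, '0');
  for (int i = 15; i >= 0; --i) {
    out[i] = digits[x & 0xF];
    x >>= 4;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fnv1a64_str(CharacterVector xs) {
  CharacterVector out(xs.size());
  for (R_xlen_t i = 0; i < xs.size(); ++i) {
    out[i] = hex64(fnv1a(std::string(xs[i])));
  }
  return out;
}

static uint64_t parse_hex(const std::string& s) {
  uint64_t x = 0;
  for (char c : s) {
    x <<= 4;
    if (c >= '0' && c <= '9') x |= (uint64_t)(c - '0');
    else if (c >= 'a' && c <= 'f') x |= (uint64_t)(c - 'a' + 10);
    else if (c >= 'A' && c <= 'F') x |= (uint64_t)(c - 'A' + 10);
    else stop("invalid hex key: %s", s.c_str());
  }
  return x;
}

// Modulo folding of 64-bit hex keys; returns 0-based indices.
// [[Rcpp::export]]
IntegerVector hex_mod64(CharacterVector keys, int n_bits) {
  if (n_bits < 1) stop("n_bits must be >= 1");
  IntegerVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    out[i] = (int)(parse_hex(std::string(keys[i])) % (uint64_t)n_bits);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Internal graph representation
// ---------------------------------------------------------------------------

struct Graph {
  int n;
  std::vector<int> Z, nH, chg, arom, ring;
  std::vector<int> bu, bv, bcode;         // bonds, 0-based endpoints
  std::vector<std::vector<std::pair<int,int>>> adj; // per atom: (neighbor, bond idx)
  std::vector<int> deg;                   // heavy degree
  std::vector<int> val10;                 // 10 * (heavy bond order sum), aromatic = 1.5
};

static Graph make_graph(const IntegerMatrix& atoms, const IntegerMatrix& bonds) {
  Graph g;
  g.n = atoms.nrow();
  g.Z.resize(g.n); g.nH.resize(g.n); g.chg.resize(g.n);
  g.arom.resize(g.n); g.ring.resize(g.n);
  for (int i = 0; i < g.n; ++i) {
    g.Z[i] = atoms(i, 0);
    g.nH[i] = atoms(i, 1);
    g.chg[i] = atoms(i, 2);
    g.arom[i] = atoms(i, 3);
    g.ring[i] = atoms(i, 4);
  }
  int m = bonds.nrow();
  g.bu.resize(m); g.bv.resize(m); g.bcode.resize(m);
  g.adj.assign(g.n, {});
  g.deg.assign(g.n, 0);
  g.val10.assign(g.n, 0);
  for (int e = 0; e < m; ++e) {
    int u = bonds(e, 0), v = bonds(e, 1), c = bonds(e, 2);
    if (u < 0 || u >= g.n || v < 0 || v >= g.n || u == v)
      stop("invalid bond endpoints");
    g.bu[e] = u; g.bv[e] = v; g.bcode[e] = c;
    g.adj[u].push_back({v, e});
    g.adj[v].push_back({u, e});
    int t = (c == 1) ? 10 : (c == 2) ? 20 : (c == 4) ? 15 : -1;
    if (t < 0) stop("invalid bond order code %d (expect 1, 2 or 4)", c);
    g.deg[u]++; g.deg[v]++;
    g.val10[u] += t; g.val10[v] += t;
  }
  return g;
}

// pi-electron count per atom: round(heavy bond order sum) - heavy degree,
// clamped at 0 (sp3 C -> 0, carbonyl C/O -> 1, aromatic ring atoms -> 1).
static std::vector<int> pi_electrons(const Graph& g) {
  std::vector<int> pi(g.n);
  for (int i = 0; i < g.n; ++i) {
    int s = (int)((g.val10[i] + 5) / 10); // round to nearest int
    pi[i] = std::max(0, s - g.deg[i]);
  }
  return pi;
}

// [[Rcpp::export]]
IntegerVector cpp_pi_electrons(IntegerMatrix atoms, IntegerMatrix bonds) {
  Graph g = make_graph(atoms, bonds);
  std::vector<int> pi = pi_electrons(g);
  return IntegerVector(pi.begin(), pi.end());
}

// Initial atom identifiers: FNV-1a of
//   "INV|Z|deg|nH|chg|ring|val10tot"
// where val10tot = 10 * (heavy bond order sum + nH).
static std::vector<uint64_t> invariants(const Graph& g) {
  std::vector<uint64_t> ids(g.n);
  for (int i = 0; i < g.n; ++i) {
    std::string s = "INV|" + std::to_string(g.Z[i]) + "|" +
      std::to_string(g.deg[i]) + "|" + std::to_string(g.nH[i]) + "|" +
      std::to_string(g.chg[i]) + "|" + std::to_string(g.ring[i]) + "|" +
      std::to_string(g.val10[i] + 10 * g.nH[i]);
    ids[i] = fnv1a(s);
  }
  return ids;
}

// [[Rcpp::export]]
CharacterVector cpp_atom_invariants(IntegerMatrix atoms, IntegerMatrix bonds) {
  Graph g = make_graph(atoms, bonds);
  std::vector<uint64_t> ids = invariants(g);
  CharacterVector out(g.n);
  for (int i = 0; i < g.n; ++i) out[i] = hex64(ids[i]);
  return out;
}

static DataFrame counts_to_df(std::map<uint64_t, int>& counts) {
  int k = counts.size();
  CharacterVector keys(k);
  IntegerVector cnt(k);
  int i = 0;
  for (auto& kv : counts) {
    keys[i] = hex64(kv.first);
    cnt[i] = kv.second;
    ++i;
  }
  return DataFrame::create(Named("key") = keys, Named("count") = cnt,
                           Named("stringsAsFactors") = false);
}

// ---------------------------------------------------------------------------
// Circular (Morgan / ECFP-style) fingerprint
// ---------------------------------------------------------------------------

// Morgan update at iteration r:
//   id_r(a) = fnv1a("ECFP|r|" + hex(id_{r-1}(a)) + "|" + join of
//             "code:hex(id_{r-1}(nbr))" sorted by (code asc, hex asc))
// Environment bond set of (a, r): bonds with min(dist(a,u), dist(a,v)) <= r-1.
// Deduplication (Rogers-Hahn style): radius-0 instances always kept; for
// r >= 1 an instance is dropped when its bond set is empty (duplicates the
// center's radius-0 instance) or equals an already-kept bond set; instances
// processed in (radius asc, identifier asc) order so the smallest radius
// survives, ties broken by smaller identifier.
// [[Rcpp::export]]
DataFrame cpp_morgan(IntegerMatrix atoms, IntegerMatrix bonds, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  Graph g = make_graph(atoms, bonds);
  std::vector<uint64_t> prev = invariants(g);

  struct Inst { int r; uint64_t id; std::vector<int> bset; int atom; };
  std::vector<Inst> inst;
  for (int a = 0; a < g.n; ++a)
    inst.push_back({0, prev[a], {}, a});

  // BFS distances from every atom (graphs are small)
  std::vector<std::vector<int>> dist(g.n, std::vector<int>(g.n, -1));
  for (int s = 0; s < g.n; ++s) {
    std::queue<int> q;
    dist[s][s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (auto& nb : g.adj[u]) {
        if (dist[s][nb.first] < 0) {
          dist[s][nb.first] = dist[s][u] + 1;
          q.push(nb.first);
        }
      }
    }
  }

  std::vector<uint64_t> cur(g.n);
  for (int r = 1; r <= radius; ++r) {
    for (int a = 0; a < g.n; ++a) {
      std::vector<std::pair<int, std::string>> nbrs;
      for (auto& nb : g.adj[a])
        nbrs.push_back({g.bcode[nb.second], hex64(prev[nb.first])});
      std::sort(nbrs.begin(), nbrs.end());
      std::string s = "ECFP|" + std::to_string(r) + "|" + hex64(prev[a]);
      for (auto& p : nbrs)
        s += "|" + std::to_string(p.first) + ":" + p.second;
      cur[a] = fnv1a(s);
      // environment bond set at radius r
      std::vector<int> bset;
      for (size_t e = 0; e < g.bu.size(); ++e) {
        int d = std::min(dist[a][g.bu[e]], dist[a][g.bv[e]]);
        if (d >= 0 && d <= r - 1) bset.push_back((int)e);
      }
      inst.push_back({r, cur[a], bset, a});
    }
    prev = cur;
  }

  std::stable_sort(inst.begin(), inst.end(), [](const Inst& x, const Inst& y) {
    if (x.r != y.r) return x.r < y.r;
    return x.id < y.id;
  });

  std::set<std::vector<int>> seen;
  std::map<uint64_t, int> counts;
  for (auto& in : inst) {
    if (in.r == 0) {
      counts[in.id]++;
    } else if (in.bset.empty()) {
      continue; // duplicates the center's radius-0 environment
    } else if (seen.insert(in.bset).second) {
      counts[in.id]++;
    }
  }
  return counts_to_df(counts);
}

// ---------------------------------------------------------------------------
// Topological torsion fingerprint
// ---------------------------------------------------------------------------

// Atom type along a path: (Z, pi electrons, heavy degree), the two path ends
// with degree decremented by 1 (path-internal bond excluded).  Path key:
//   fnv1a("TT|Z,pi,d|Z,pi,d|...") for the lexicographically smaller of the
// forward/reverse type-triple sequence.
// [[Rcpp::export]]
DataFrame cpp_torsion(IntegerMatrix atoms, IntegerMatrix bonds, int path_len) {
  if (path_len < 2) stop("path_length must be >= 2");
  Graph g = make_graph(atoms, bonds);
  std::vector<int> pi = pi_electrons(g);
  std::map<uint64_t, int> counts;

  std::vector<int> path;
  std::vector<char> used(g.n, 0);

  std::function<void(int)> dfs = [&](int u) {
    path.push_back(u); used[u] = 1;
    if ((int)path.size() == path_len) {
      if (path.front() < path.back()) { // each undirected path once
        std::vector<std::array<int,3>> fwd, rev;
        int L = path_len;
        for (int i = 0; i < L; ++i) {
          int a = path[i];
          int d = g.deg[a] - ((i == 0 || i == L - 1) ? 1 : 0);
          fwd.push_back({g.Z[a], pi[a], d});
        }
        rev.assign(fwd.rbegin(), fwd.rend());
        const std::vector<std::array<int,3>>& can = (rev < fwd) ? rev : fwd;
        std::string s = "TT";
        for (auto& t : can)
          s += "|" + std::to_string(t[0]) + "," + std::to_string(t[1]) + "," +
               std::to_string(t[2]);
        counts[fnv1a(s)]++;
      }
    } else {
      for (auto& nb : g.adj[u])
        if (!used[nb.first]) dfs(nb.first);
    }
    used[u] = 0; path.pop_back();
  };

  for (int a = 0; a < g.n; ++a) dfs(a);
  return counts_to_df(counts);
}

// ---------------------------------------------------------------------------
// All-connected-subgraph fingerprint
// ---------------------------------------------------------------------------

// Canonical form of a small labeled subgraph by branch-and-prune minimization
// over vertex orderings.  Serialization: per placed vertex a "column" =
// [label, edge codes to each previously placed vertex], where label =
// Z*1000 + (charge+10)*10 + aromatic and edge codes are single=1, double=2,
// aromatic=3, absent=9 (absent sorts last so connected placements win).
// Canonical serialization is the lexicographic minimum; only minimal-column
// candidates are branched on at each position.
struct Canon {
  int nv;
  std::vector<int> lab;
  std::vector<std::vector<int>> ecode; // nv x nv, 9 if absent
  std::vector<int> best;
  bool have_best;

  void search(std::vector<int>& order, std::vector<char>& used,
              std::vector<int>& serial) {
    int placed = order.size();
    if (placed == nv) {
      if (!have_best || serial < best) { best = serial; have_best = true; }
      return;
    }
    // compute candidate columns
    std::vector<int> min_col;
    std::vector<int> cand;
    for (int v = 0; v < nv; ++v) {
      if (used[v]) continue;
      std::vector<int> col;
      col.push_back(lab[v]);
      for (int j = 0; j < placed; ++j) col.push_back(ecode[v][order[j]]);
      if (cand.empty() || col < min_col) {
        min_col = col; cand.clear(); cand.push_back(v);
      } else if (col == min_col) {
        cand.push_back(v);
      }
    }
    size_t base = serial.size();
    for (int v : cand) {
      serial.insert(serial.end(), min_col.begin(), min_col.end());
      order.push_back(v); used[v] = 1;
      search(order, used, serial);
      used[v] = 0; order.pop_back();
      serial.resize(base);
    }
  }
};

static uint64_t subgraph_key(const Graph& g, const std::vector<int>& edges) {
  // collect vertices
  std::vector<int> verts;
  for (int e : edges) { verts.push_back(g.bu[e]); verts.push_back(g.bv[e]); }
  std::sort(verts.begin(), verts.end());
  verts.erase(std::unique(verts.begin(), verts.end()), verts.end());
  int nv = verts.size();
  std::unordered_map<int,int> vid;
  for (int i = 0; i < nv; ++i) vid[verts[i]] = i;

  Canon c;
  c.nv = nv;
  c.lab.resize(nv);
  for (int i = 0; i < nv; ++i) {
    int a = verts[i];
    c.lab[i] = g.Z[a] * 1000 + (g.chg[a] + 10) * 10 + g.arom[a];
  }
  c.ecode.assign(nv, std::vector<int>(nv, 9));
  for (int e : edges) {
    int u = vid[g.bu[e]], v = vid[g.bv[e]];
    int code = (g.bcode[e] == 1) ? 1 : (g.bcode[e] == 2) ? 2 : 3;
    c.ecode[u][v] = c.ecode[v][u] = code;
  }
  c.have_best = false;
  std::vector<int> order, serial;
  std::vector<char> used(nv, 0);
  order.reserve(nv);
  c.search(order, used, serial);

  std::string s = "SG";
  for (int x : c.best) s += "|" + std::to_string(x);
  return fnv1a(s);
}

// [[Rcpp::export]]
CharacterVector cpp_subgraph_canonical_key(IntegerMatrix atoms,
                                           IntegerMatrix bonds,
                                           IntegerVector edge_idx) {
  Graph g = make_graph(atoms, bonds);
  std::vector<int> edges(edge_idx.begin(), edge_idx.end());
  return CharacterVector::create(hex64(subgraph_key(g, edges)));
}

// Enumeration A: each connected edge-induced subgraph with 1..max_bonds
// bonds exactly once, by anchoring at its minimum edge index and extending
// with candidate exclusion (no deduplication set needed).
// [[Rcpp::export]]
DataFrame cpp_subgraph(IntegerMatrix atoms, IntegerMatrix bonds,
                       int max_bonds, double cap) {
  if (max_bonds < 1) stop("max_bonds must be >= 1");
  Graph g = make_graph(atoms, bonds);
  int m = g.bu.size();
  std::map<uint64_t, int> counts;
  double n_inst = 0;

  std::vector<int> S;
  std::vector<char> inS(m, 0), forbidden(m, 0);
  std::vector<char> inV(g.n, 0);

  std::function<void()> extend = [&]() {
    n_inst += 1;
    if (n_inst > cap) stop("subgraph enumeration exceeded cap of %g instances", cap);
    counts[subgraph_key(g, S)]++;
    if ((int)S.size() == max_bonds) return;
    // candidate edges adjacent to current vertex set, not in S, not forbidden
    std::vector<int> cand;
    std::vector<char> in_cand(g.bu.size(), 0);
    for (int v = 0; v < g.n; ++v) {
      if (!inV[v]) continue;
      for (auto& nb : g.adj[v]) {
        int e = nb.second;
        if (!inS[e] && !forbidden[e] && !in_cand[e]) {
          cand.push_back(e); in_cand[e] = 1;
        }
      }
    }
    // the i-th branch includes candidate i and permanently forbids
    // candidates 0..i-1 in its subtree (exactly-once enumeration)
    for (size_t i = 0; i < cand.size(); ++i) {
      int e = cand[i];
      inS[e] = 1; S.push_back(e);
      int u = g.bu[e], v = g.bv[e];
      int addu = !inV[u], addv = !inV[v];
      inV[u] = 1; inV[v] = 1;
      extend();
      if (addu) inV[u] = 0;
      if (addv) inV[v] = 0;
      S.pop_back(); inS[e] = 0;
      forbidden[e] = 1;
    }
    for (int e : cand) forbidden[e] = 0;
  };

  std::vector<char> base_forbidden(m, 0);
  for (int e0 = 0; e0 < m; ++e0) {
    // subgraphs whose minimum edge is e0: forbid all smaller edges
    std::fill(forbidden.begin(), forbidden.end(), 0);
    for (int e = 0; e < e0; ++e) forbidden[e] = 1;
    S.assign(1, e0); inS.assign(m, 0); inS[e0] = 1;
    std::fill(inV.begin(), inV.end(), 0);
    inV[g.bu[e0]] = 1; inV[g.bv[e0]] = 1;
    extend();
  }
  return counts_to_df(counts);
}

// Enumeration B (oracle): breadth-first closure over edge-subset bitmasks
// with a visited set; independent of enumeration A.  256-bit edge masks.
struct EdgeMask {
  std::array<uint64_t, 4> w{};
  bool operator==(const EdgeMask& o) const { return w == o.w; }
  void set(int e) { w[e >> 6] |= (1ULL << (e & 63)); }
  bool get(int e) const { return (w[e >> 6] >> (e & 63)) & 1; }
};
struct EdgeMaskHash {
  size_t operator()(const EdgeMask& m) const {
    uint64_t h = FNV_OFFSET;
    for (uint64_t x : m.w) { h ^= x; h *= FNV_PRIME; }
    return (size_t)h;
  }
};

// [[Rcpp::export]]
DataFrame cpp_subgraph_oracle(IntegerMatrix atoms, IntegerMatrix bonds,
                              int max_bonds, double cap) {
  if (max_bonds < 1) stop("max_bonds must be >= 1");
  Graph g = make_graph(atoms, bonds);
  int m = g.bu.size();
  if (m > 256) stop("oracle-scope error: more than 256 bonds (%d)", m);

  std::unordered_set<EdgeMask, EdgeMaskHash> visited;
  std::queue<std::pair<EdgeMask,int>> q; // (mask, popcount)
  for (int e = 0; e < m; ++e) {
    EdgeMask mask;
    mask.set(e);
    visited.insert(mask);
    q.push({mask, 1});
  }
  std::map<uint64_t, int> counts;
  while (!q.empty()) {
    auto [mask, k] = q.front(); q.pop();
    std::vector<int> edges;
    for (int e = 0; e < m; ++e) if (mask.get(e)) edges.push_back(e);
    counts[subgraph_key(g, edges)]++;
    if ((double)visited.size() > cap)
      stop("oracle-scope error: instance cap %g exceeded", cap);
    if (k == max_bonds) continue;
    // expand by any edge sharing a vertex with the subgraph
    std::set<int> verts;
    for (int e : edges) { verts.insert(g.bu[e]); verts.insert(g.bv[e]); }
    for (int v : verts) {
      for (auto& nb : g.adj[v]) {
        int e = nb.second;
        if (!mask.get(e)) {
          EdgeMask nm = mask;
          nm.set(e);
          if (visited.insert(nm).second) q.push({nm, k + 1});
        }
      }
    }
  }
  return counts_to_df(counts);
}

// Ring membership: an atom is in a ring iff it is incident to a non-bridge
// edge.  Bridges found by DFS lowpoint computation.
// [[Rcpp::export]]
LogicalVector cpp_ring_atoms(int n_atoms, IntegerMatrix bonds) {
  int n = n_atoms, m = bonds.nrow();
  std::vector<std::vector<std::pair<int,int>>> adj(n);
  for (int e = 0; e < m; ++e) {
    int u = bonds(e, 0), v = bonds(e, 1);
    adj[u].push_back({v, e});
    adj[v].push_back({u, e});
  }
  std::vector<int> disc(n, -1), low(n, 0);
  std::vector<char> is_bridge(m, 0);
  int timer = 0;
  std::function<void(int,int)> dfs = [&](int u, int pe) {
    disc[u] = low[u] = timer++;
    for (auto& nb : adj[u]) {
      int v = nb.first, e = nb.second;
      if (e == pe) continue;
      if (disc[v] >= 0) {
        low[u] = std::min(low[u], disc[v]);
      } else {
        dfs(v, e);
        low[u] = std::min(low[u], low[v]);
        if (low[v] > disc[u]) is_bridge[e] = 1;
      }
    }
  };
  for (int s = 0; s < n; ++s) if (disc[s] < 0) dfs(s, -1);
  LogicalVector ring(n, false);
  for (int e = 0; e < m; ++e) {
    if (!is_bridge[e]) { ring[bonds(e, 0)] = true; ring[bonds(e, 1)] = true; }
  }
  return ring;
}

// ---------------------------------------------------------------------------
// Seed stream
// ---------------------------------------------------------------------------

// splitmix64-derived stream of 31-bit seeds from a master seed.
// [[Rcpp::export]]
NumericVector cpp_splitmix_seeds(double master, int n) {
  uint64_t x = (uint64_t)((int64_t)master);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    out[i] = (double)(z >> 33); // 31-bit non-negative seed
  }
  return out;
}
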