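// Graphlet orbit counting: ESU enumeration of connected induced subgraphs
// of 2-5 nodes, classified into automorphism orbits via marked-vertex
// canonical codes looked up in tables built on the R side
// (graphlet_catalog()).

#include <Rcpp.h>
#include <climits>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// bit index of pair (i, j), i < j, in a k-node adjacency code
inline int pair_bit(int i, int j, int k) {
  return i * k - i * (i + 1) / 2 + (j - i - 1);
}

struct OrbitCounter {
  int n;
  std::vector<std::vector<int>> adj;           // sorted neighbour lists
  std::unordered_set<long long> edge_set;      // a * n + b, a < b
  std::vector<std::unordered_map<int, int>> lookup;  // per k (2..5)
  IntegerMatrix counts;
  int kmax;

  // permutations of 0..m-1 for m = 1..4
  std::vector<std::vector<std::vector<int>>> perms;

  OrbitCounter(int n_, int n_orbits, int kmax_)
      : n(n_), adj(n_), lookup(6), counts(n_, n_orbits), kmax(kmax_),
        perms(5) {
    for (int m = 1; m <= 4; ++m) {
      std::vector<int> p(m);
      for (int i = 0; i < m; ++i) p[i] = i;
      do {
        perms[m].push_back(p);
      } while (std::next_permutation(p.begin(), p.end()));
    }
  }

  inline bool has_edge(int a, int b) const {
    if (a > b) std::swap(a, b);
    return edge_set.count((long long)a * n + b) > 0;
  }

  void process(const std::vector<int>& vs) {
    int k = (int)vs.size();
    bool local[5][5] = {{false}};
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j)
        local[i][j] = local[j][i] = has_edge(vs[i], vs[j]);

    const auto& pp = perms[k - 1];
    for (int p = 0; p < k; ++p) {
      // order = (p, others permuted); minimize the adjacency code
      int others[4];
      int m = 0;
      for (int i = 0; i < k; ++i)
        if (i != p) others[m++] = i;
      int best = INT_MAX;
      int ord[5];
      ord[0] = p;
      for (const auto& perm : pp) {
        for (int i = 0; i < m; ++i) ord[i + 1] = others[perm[i]];
        int code = 0;
        for (int i = 0; i < k; ++i)
          for (int j = i + 1; j < k; ++j)
            if (local[ord[i]][ord[j]]) code |= 1 << pair_bit(i, j, k);
        if (code < best) best = code;
      }
      auto it = lookup[k].find(best);
      if (it == lookup[k].end())
        stop("internal error: unknown marked canonical code");
      counts(vs[p], it->second) += 1;
    }
  }

  // Wernicke's ESU: each connected k-node induced subgraph exactly once.
  void extend(std::vector<int>& sub, std::vector<int>& ext, int v, int k,
              std::unordered_set<int>& closed) {
    if ((int)sub.size() == k) {
      process(sub);
      return;
    }
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      std::vector<int> added;
      for (int u : adj[w]) {
        if (u > v && !closed.count(u)) {
          ext2.push_back(u);
          added.push_back(u);
          closed.insert(u);  // exclusive neighbourhood bookkeeping
        }
      }
      sub.push_back(w);
      extend(sub, ext2, v, k, closed);
      sub.pop_back();
      for (int u : added) closed.erase(u);
    }
  }

  void run() {
    for (int k = 2; k <= kmax; ++k) {
      for (int v = 0; v < n; ++v) {
        std::vector<int> sub{v};
        std::vector<int> ext;
        std::unordered_set<int> closed;
        closed.insert(v);
        for (int u : adj[v])
          if (u > v) {
            ext.push_back(u);
            closed.insert(u);
          }
        extend(sub, ext, v, k, closed);
        // 'closed' discarded per root vertex
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix orbit_counts_cpp(int n, IntegerMatrix edges, List lookup,
                               int n_orbits, int kmax) {
  OrbitCounter oc(n, n_orbits, kmax);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    if (a == b) continue;
    if (a > b) std::swap(a, b);
    if (oc.edge_set.insert((long long)a * n + b).second) {
      oc.adj[a].push_back(b);
      oc.adj[b].push_back(a);
    }
  }
  for (auto& nb : oc.adj) std::sort(nb.begin(), nb.end());
  for (int k = 2; k <= kmax; ++k) {
    List lk = lookup[k - 2];
    IntegerVector codes = lk["codes"];
    IntegerVector orbits = lk["orbits"];
    for (int i = 0; i < codes.size(); ++i)
      oc.lookup[k][codes[i]] = orbits[i];
  }
  oc.run();
  return oc.counts;
}
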