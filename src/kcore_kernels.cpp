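// Compiled kernels for k-core peeling and minimal k-core enumeration.
//
// Vertex subsets are bit masks (vectors of 64-bit words) so induced degrees
// are popcounts; this keeps the exponential backtracking search affordable
// at the graph sizes the simulation study uses (n up to a few tens).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <set>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

static inline bool test_bit(const uint64_t *m, int v) {
  return (m[v >> 6] >> (v & 63)) & 1ull;
}
static inline void set_bit(uint64_t *m, int v) { m[v >> 6] |= 1ull << (v & 63); }
static inline void clear_bit(uint64_t *m, int v) { m[v >> 6] &= ~(1ull << (v & 63)); }

namespace {

struct BitGraph {
  int n, W;
  std::vector<uint64_t> adj; // n rows of W words

  explicit BitGraph(const List &adj_list) {
    n = adj_list.size();
    W = std::max(1, (n + 63) / 64);
    adj.assign(static_cast<size_t>(n) * W, 0ull);
    for (int v = 0; v < n; ++v) {
      IntegerVector nb = adj_list[v];
      for (int i = 0; i < nb.size(); ++i) set_bit(row(v), nb[i] - 1);
    }
  }
  uint64_t *row(int v) { return &adj[static_cast<size_t>(v) * W]; }
  const uint64_t *row(int v) const { return &adj[static_cast<size_t>(v) * W]; }

  int deg_in(int v, const uint64_t *mask) const {
    const uint64_t *r = row(v);
    int c = 0;
    for (int i = 0; i < W; ++i) c += __builtin_popcountll(r[i] & mask[i]);
    return c;
  }
  // In-place peel: repeatedly drop vertices with induced degree < k.
  void peel(uint64_t *mask, int k) const {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int v = 0; v < n; ++v)
        if (test_bit(mask, v) && deg_in(v, mask) < k) {
          clear_bit(mask, v);
          changed = true;
        }
    }
  }
};

inline bool any_bit(const uint64_t *m, int W) {
  for (int i = 0; i < W; ++i)
    if (m[i]) return true;
  return false;
}

IntegerVector mask_to_ids(const uint64_t *mask, int n) {
  std::vector<int> out;
  for (int v = 0; v < n; ++v)
    if (test_bit(mask, v)) out.push_back(v + 1);
  return wrap(out);
}

} // namespace

// Greedy maximum k-core peel with removal order (minimum degree first,
// ties broken on smallest vertex id).  `sub` is the 1-based vertex subset
// the graph is restricted to before peeling.
// [[Rcpp::export(name = ".cpp_peel")]]
List cpp_peel(List adj_list, IntegerVector sub, int k) {
  int n = adj_list.size();
  std::vector<char> in(n, 0);
  for (int i = 0; i < sub.size(); ++i) in[sub[i] - 1] = 1;
  std::vector<std::vector<int>> adj(n);
  for (int v = 0; v < n; ++v) {
    if (!in[v]) continue;
    IntegerVector nb = adj_list[v];
    for (int i = 0; i < nb.size(); ++i)
      if (in[nb[i] - 1]) adj[v].push_back(nb[i] - 1);
  }
  std::vector<int> deg(n, 0);
  std::set<std::pair<int, int>> pq; // (degree, id): min degree, then min id
  for (int v = 0; v < n; ++v)
    if (in[v]) {
      deg[v] = static_cast<int>(adj[v].size());
      pq.insert({deg[v], v});
    }
  std::vector<int> rem_v, rem_d;
  while (!pq.empty()) {
    auto it = pq.begin();
    if (it->first >= k) break; // minimum degree meets the threshold
    int v = it->second;
    pq.erase(it);
    in[v] = 0;
    rem_v.push_back(v + 1);
    rem_d.push_back(deg[v]);
    for (int u : adj[v])
      if (in[u]) {
        pq.erase({deg[u], u});
        --deg[u];
        pq.insert({deg[u], u});
      }
  }
  std::vector<int> core;
  for (auto &pr : pq) core.push_back(pr.second + 1);
  std::sort(core.begin(), core.end());
  return List::create(_["core"] = wrap(core), _["removed"] = wrap(rem_v),
                      _["removed_degree"] = wrap(rem_d));
}

namespace {

struct Enumerator {
  const BitGraph &G;
  int k, W;
  long long max_cores;
  long long nodes = 0;
  bool truncated = false;
  std::vector<std::vector<int>> cores;

  Enumerator(const BitGraph &g, int k_, long long mc)
      : G(g), k(k_), W(g.W), max_cores(mc) {}

  void report(const uint64_t *kcore) {
    std::vector<int> ids;
    for (int v = 0; v < G.n; ++v)
      if (test_bit(kcore, v)) ids.push_back(v + 1);
    cores.push_back(std::move(ids));
    if (max_cores > 0 && static_cast<long long>(cores.size()) >= max_cores)
      truncated = true;
  }

  // One node of the backtracking search tree.  `kcore` always holds a peeled
  // k-core; `notset` the vertices that may not be deleted below this node.
  void extension(const uint64_t *kcore, std::vector<uint64_t> notset) {
    if (truncated) return;
    ++nodes;
    int n = G.n;
    // Peel every single-vertex deletion once; reuse for the minimality test,
    // the candidate set and the child states.
    std::vector<uint64_t> children(static_cast<size_t>(n) * W, 0ull);
    std::vector<std::pair<int, int>> cand; // (induced degree, id) ascending
    bool all_empty = true;
    for (int v = 0; v < n; ++v) {
      if (!test_bit(kcore, v)) continue;
      uint64_t *ch = &children[static_cast<size_t>(v) * W];
      std::copy(kcore, kcore + W, ch);
      clear_bit(ch, v);
      G.peel(ch, k);
      if (any_bit(ch, W)) {
        all_empty = false;
        if (!test_bit(notset.data(), v)) cand.push_back({G.deg_in(v, kcore), v});
      }
    }
    if (all_empty) { // no proper subset induces a k-core: minimal
      report(kcore);
      return;
    }
    std::sort(cand.begin(), cand.end());
    for (auto &pr : cand) {
      if (truncated) return;
      int s = pr.second;
      const uint64_t *ch = &children[static_cast<size_t>(s) * W];
      // Prune if peeling the child evicted a member of `not`: every minimal
      // k-core below such a child was already reported in an earlier branch.
      bool evicted = false;
      for (int i = 0; i < W; ++i)
        if (notset[i] & ~ch[i]) { evicted = true; break; }
      if (!evicted) extension(ch, notset);
      set_bit(notset.data(), s);
    }
  }
};

} // namespace

// Backtracking enumeration of all minimal k-cores.
// [[Rcpp::export(name = ".cpp_enumerate")]]
List cpp_enumerate(List adj_list, int k, double max_cores = -1) {
  BitGraph G(adj_list);
  std::vector<uint64_t> root(G.W, 0ull);
  for (int v = 0; v < G.n; ++v) set_bit(root.data(), v);
  G.peel(root.data(), k);
  Enumerator E(G, k, static_cast<long long>(max_cores));
  if (any_bit(root.data(), G.W))
    E.extension(root.data(), std::vector<uint64_t>(G.W, 0ull));
  List cores(E.cores.size());
  for (size_t i = 0; i < E.cores.size(); ++i) cores[i] = wrap(E.cores[i]);
  return List::create(_["cores"] = cores, _["nodes"] = static_cast<double>(E.nodes),
                      _["truncated"] = E.truncated);
}

// Exhaustive oracle: scan all vertex subsets (n <= 20 enforced in R), keep
// the k-cores, then keep those containing no smaller k-core.
// [[Rcpp::export(name = ".cpp_subset_oracle")]]
List cpp_subset_oracle(List adj_list, int k) {
  int n = adj_list.size();
  if (n > 25) stop("subset oracle limited to 25 vertices");
  std::vector<uint32_t> adj(n, 0u);
  for (int v = 0; v < n; ++v) {
    IntegerVector nb = adj_list[v];
    for (int i = 0; i < nb.size(); ++i) adj[v] |= 1u << (nb[i] - 1);
  }
  std::vector<uint32_t> kcores;
  uint32_t full = (n == 32) ? ~0u : ((1u << n) - 1u);
  for (uint32_t m = 1;; ++m) {
    bool ok = true;
    for (int v = 0; v < n && ok; ++v)
      if ((m >> v) & 1u)
        if (__builtin_popcount(adj[v] & m) < k) ok = false;
    if (ok) kcores.push_back(m);
    if (m == full) break;
  }
  std::sort(kcores.begin(), kcores.end(),
            [](uint32_t a, uint32_t b) {
              int pa = __builtin_popcount(a), pb = __builtin_popcount(b);
              return pa != pb ? pa < pb : a < b;
            });
  std::vector<uint32_t> minimal;
  for (uint32_t m : kcores) {
    bool has_sub = false;
    for (uint32_t s : minimal) {
      if (__builtin_popcount(s) >= __builtin_popcount(m)) break;
      if ((s & ~m) == 0u) { has_sub = true; break; }
    }
    // a non-minimal k-core always contains a *minimal* one, so checking the
    // minimal list found so far (in increasing size) suffices
    if (!has_sub) minimal.push_back(m);
  }
  List out(minimal.size());
  for (size_t i = 0; i < minimal.size(); ++i) {
    std::vector<int> ids;
    for (int v = 0; v < n; ++v)
      if ((minimal[i] >> v) & 1u) ids.push_back(v + 1);
    out[i] = wrap(ids);
  }
  return out;
}

namespace {

struct NaiveEnum {
  const BitGraph &G;
  int k;
  bool memoize;
  std::unordered_set<uint64_t> seen;
  std::vector<uint64_t> found;
  long long reports = 0, visits = 0;

  NaiveEnum(const BitGraph &g, int k_, bool mem) : G(g), k(k_), memoize(mem) {}

  uint64_t peel1(uint64_t S) const {
    std::vector<uint64_t> m(1, S);
    G.peel(m.data(), k);
    return m[0];
  }
  // S is already a k-core; minimal iff every single deletion peels to empty.
  bool is_minimal(uint64_t S) const {
    for (int v = 0; v < G.n; ++v)
      if (test_bit(&S, v)) {
        uint64_t T = S;
        clear_bit(&T, v);
        if (peel1(T)) return false;
      }
    return true;
  }
  void visit(uint64_t S) {
    uint64_t H = peel1(S); // the maximum k-core of the current graph
    if (!H) return;
    if (memoize && !seen.insert(H).second) return;
    ++visits;
    if (visits > 200000000LL) stop("naive enumeration exceeded its node budget");
    if (is_minimal(H)) {
      ++reports;
      found.push_back(H);
      return;
    }
    for (int v = 0; v < G.n; ++v)
      if (test_bit(&H, v)) {
        uint64_t T = H;
        clear_bit(&T, v);
        visit(T);
      }
  }
};

} // namespace

// Branching baseline: delete each vertex of the maximum k-core in turn and
// recurse, reporting whenever the current graph itself is a minimal k-core.
// May report the same core repeatedly; duplicates are removed at the end.
// [[Rcpp::export(name = ".cpp_naive")]]
List cpp_naive(List adj_list, int k, bool memoize) {
  BitGraph G(adj_list);
  if (G.n > 64) stop("naive enumeration limited to 64 vertices");
  uint64_t full = (G.n == 64) ? ~0ull : ((1ull << G.n) - 1ull);
  NaiveEnum E(G, k, memoize);
  E.visit(full);
  std::vector<uint64_t> uniq = E.found;
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  List cores(uniq.size());
  for (size_t i = 0; i < uniq.size(); ++i) {
    std::vector<int> ids;
    for (int v = 0; v < G.n; ++v)
      if ((uniq[i] >> v) & 1ull) ids.push_back(v + 1);
    cores[i] = wrap(ids);
  }
  return List::create(_["cores"] = cores,
                      _["reports"] = static_cast<double>(E.reports),
                      _["visits"] = static_cast<double>(E.visits));
}
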