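#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact maximum common connected-subgraph search.
//
// A mapping pairs substrate atom i with product atom j when compat(i,j)
// (same element). Induced consistency: for every mapped pair (k, k') a bond
// i-k exists iff a bond j-k' exists (orders are not compared). Every added
// pair after the first must be adjacent, through a bond present on both
// sides, to an already mapped pair (connected extension). Candidates are
// explored in lexicographic (i, j) order with an exclusion set so each
// mapping is enumerated once; a reachability bound prunes branches that
// cannot beat the incumbent; among maximum mappings the lexicographically
// smallest (substrate, product) pair sequence wins.

namespace {

struct McsState {
  int ns, np;
  const int *adjS, *adjP, *compat; // ns*ns, np*np, ns*np (column-major from R)
  std::vector<int> ms, mp;         // 1-based partner or 0
  int size;
  int bestSize;
  std::vector<int> bestPairs;      // flattened (i, j) sorted by i
  std::vector<int> curPairs;       // scratch

  inline bool aS(int i, int k) const { return adjS[i + ns * k] != 0; }
  inline bool aP(int j, int l) const { return adjP[j + np * l] != 0; }
  inline bool cmp(int i, int j) const { return compat[i + ns * j] != 0; }

  int reach(const std::vector<int> &map, const int *adj, int n) const {
    bool anyMapped = false;
    for (int v = 0; v < n; ++v) if (map[v]) { anyMapped = true; break; }
    if (!anyMapped) return n;
    std::vector<char> seen(n, 0);
    std::vector<int> queue;
    for (int v = 0; v < n; ++v) {
      if (map[v]) continue;
      for (int u = 0; u < n; ++u)
        if (map[u] && adj[v + n * u]) { seen[v] = 1; queue.push_back(v); break; }
    }
    for (size_t h = 0; h < queue.size(); ++h) {
      int v = queue[h];
      for (int u = 0; u < n; ++u)
        if (adj[v + n * u] && !seen[u] && !map[u]) { seen[u] = 1; queue.push_back(u); }
    }
    int c = 0;
    for (int v = 0; v < n; ++v) c += seen[v];
    return c;
  }

  void consider() {
    if (size < bestSize) return;
    curPairs.clear();
    for (int i = 0; i < ns; ++i)
      if (ms[i]) { curPairs.push_back(i); curPairs.push_back(ms[i] - 1); }
    if (size > bestSize) { bestSize = size; bestPairs = curPairs; return; }
    for (size_t k = 0; k < curPairs.size(); ++k) {
      if (curPairs[k] < bestPairs[k]) { bestPairs = curPairs; return; }
      if (curPairs[k] > bestPairs[k]) return;
    }
  }

  void rec(std::vector<char> banned) {
    int ub = size + std::min(reach(ms, adjS, ns), reach(mp, adjP, np));
    if (ub < bestSize) return;
    bool extended = false;
    for (int i = 0; i < ns; ++i) {
      if (ms[i]) continue;
      for (int j = 0; j < np; ++j) {
        if (mp[j] || !cmp(i, j) || banned[i + ns * j]) continue;
        bool ok = true, touch = false, haveMapped = false;
        for (int k = 0; k < ns; ++k) {
          if (!ms[k]) continue;
          haveMapped = true;
          bool bs = aS(i, k), bp = aP(j, ms[k] - 1);
          if (bs != bp) { ok = false; break; }
          if (bs) touch = true;
        }
        if (!ok || (haveMapped && !touch)) continue;
        ms[i] = j + 1; mp[j] = i + 1; ++size;
        rec(banned);
        ms[i] = 0; mp[j] = 0; --size;
        banned[i + ns * j] = 1;
        extended = true;
        int ub2 = size + std::min(reach(ms, adjS, ns), reach(mp, adjP, np));
        if (ub2 < bestSize) return;
      }
    }
    if (!extended) consider();
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix mcs_exact_cpp(IntegerMatrix adjS, IntegerMatrix adjP,
                            IntegerMatrix compat) {
  McsState st;
  st.ns = adjS.nrow();
  st.np = adjP.nrow();
  st.adjS = adjS.begin();
  st.adjP = adjP.begin();
  st.compat = compat.begin();
  st.ms.assign(st.ns, 0);
  st.mp.assign(st.np, 0);
  st.size = 0;
  st.bestSize = 0;
  if (st.ns > 0 && st.np > 0)
    st.rec(std::vector<char>(st.ns * st.np, 0));
  int n = st.bestSize;
  IntegerMatrix out(n, 2);
  for (int r = 0; r < n; ++r) {
    out(r, 0) = st.bestPairs[2 * r] + 1;
    out(r, 1) = st.bestPairs[2 * r + 1] + 1;
  }
  return out;
}
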