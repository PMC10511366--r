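#include <Rcpp.h>
#include <vector>
#include <deque>
#include <limits>
using namespace Rcpp;

// Boykov-Kolmogorov max-flow / min-cut on a directed graph with double
// capacities, tailored to the optimal-surface cut graphs built in R
// (tens of thousands of nodes, ~10^6 arcs, short augmenting paths).
// Returns the max-flow value and the source-side membership of the minimum
// cut (the final source search tree).

// [[Rcpp::export]]
List cpp_maxflow(IntegerVector from, IntegerVector to, NumericVector cap,
                 int nNodes, int source, int sink) {
  const int m = from.size();
  std::vector<int> head(2 * (size_t)m), nxt(2 * (size_t)m);
  std::vector<double> res(2 * (size_t)m);
  std::vector<int> first(nNodes, -1);
  for (int i = 0; i < m; ++i) {
    int u = from[i] - 1, v = to[i] - 1;
    int a = 2 * i, b = 2 * i + 1;
    head[a] = v; res[a] = cap[i]; nxt[a] = first[u]; first[u] = a;
    head[b] = u; res[b] = 0.0;    nxt[b] = first[v]; first[v] = b;
  }
  const int s = source - 1, t = sink - 1;
  const double EPS = 1e-9;
  const int FREE = 0, SRC = 1, SNK = 2;
  std::vector<char> tree(nNodes, FREE), active(nNodes, 0);
  std::vector<int> parentArc(nNodes, -1);   // arc from node to its parent
  std::vector<int> dist(nNodes, 0);
  std::vector<unsigned> ts(nNodes, 0);
  unsigned TIME = 0;
  std::deque<int> act, orphans;
  double flow = 0.0;

  tree[s] = SRC; tree[t] = SNK;
  ts[s] = ts[t] = 0; dist[s] = dist[t] = 0;
  auto pushActive = [&](int v) {
    if (!active[v]) { active[v] = 1; act.push_back(v); }
  };
  pushActive(s); pushActive(t);

  // residual of the tree arc from p toward q (growth direction)
  auto growResid = [&](int p, int a) -> double {
    return tree[p] == SRC ? res[a] : res[a ^ 1];
  };

  // is q connected to a terminal through valid parents? caches via TIME/dist
  auto validOrigin = [&](int q) -> bool {
    int u = q, steps = 0;
    while (true) {
      if (u == s || u == t) break;
      if (ts[u] == TIME) { steps += dist[u]; break; }
      if (parentArc[u] < 0) return false;
      ++steps;
      u = head[parentArc[u]];
    }
    // mark the walked prefix as checked at this TIME
    int u2 = q, d = steps;
    while (u2 != u) {
      ts[u2] = TIME; dist[u2] = d--;
      u2 = head[parentArc[u2]];
    }
    return true;
  };

  while (true) {
    // ---- growth ----
    int bridge = -1;
    while (!act.empty()) {
      int p = act.front();
      if (tree[p] == FREE) { act.pop_front(); active[p] = 0; continue; }
      bool found = false;
      for (int a = first[p]; a != -1; a = nxt[a]) {
        if (growResid(p, a) <= EPS) continue;
        int q = head[a];
        if (tree[q] == FREE) {
          tree[q] = tree[p];
          parentArc[q] = a ^ 1;           // arc q -> p
          dist[q] = dist[p] + 1; ts[q] = ts[p];
          pushActive(q);
        } else if (tree[q] != tree[p]) {
          bridge = (tree[p] == SRC) ? a : (a ^ 1);
          found = true;
          break;
        }
      }
      if (found) break;
      act.pop_front(); active[p] = 0;
    }
    if (bridge < 0) break;

    // ---- augment along s ... bridge ... t ----
    ++TIME;
    double bn = res[bridge];
    int u = head[bridge ^ 1];             // tail (source side)
    while (u != s) {
      int pa = parentArc[u];              // u -> parent; flow runs parent -> u
      bn = std::min(bn, res[pa ^ 1]);
      u = head[pa];
    }
    u = head[bridge];                     // head (sink side)
    while (u != t) {
      int pa = parentArc[u];              // flow runs u -> parent
      bn = std::min(bn, res[pa]);
      u = head[pa];
    }
    res[bridge] -= bn; res[bridge ^ 1] += bn;
    flow += bn;
    u = head[bridge ^ 1];
    while (u != s) {
      int pa = parentArc[u];
      res[pa ^ 1] -= bn; res[pa] += bn;
      if (res[pa ^ 1] <= EPS) { parentArc[u] = -1; orphans.push_back(u); }
      u = head[pa];
    }
    u = head[bridge];
    while (u != t) {
      int pa = parentArc[u];
      res[pa] -= bn; res[pa ^ 1] += bn;
      if (res[pa] <= EPS) { parentArc[u] = -1; orphans.push_back(u); }
      u = head[pa];
    }

    // ---- adoption ----
    while (!orphans.empty()) {
      int o = orphans.front(); orphans.pop_front();
      char myTree = tree[o];
      int bestArc = -1, bestDist = std::numeric_limits<int>::max();
      for (int a = first[o]; a != -1; a = nxt[a]) {
        int q = head[a];
        if (tree[q] != myTree) continue;
        // need residual from q toward o: for SRC tree flow q -> o
        double r = (myTree == SRC) ? res[a ^ 1] : res[a];
        if (r <= EPS) continue;
        if (!validOrigin(q)) continue;
        if (dist[q] + 1 < bestDist) { bestDist = dist[q] + 1; bestArc = a; }
      }
      if (bestArc >= 0) {
        parentArc[o] = bestArc;
        dist[o] = bestDist; ts[o] = TIME;
      } else {
        tree[o] = FREE;
        for (int a = first[o]; a != -1; a = nxt[a]) {
          int q = head[a];
          if (tree[q] != myTree) continue;
          if (parentArc[q] >= 0 && head[parentArc[q]] == o) {
            parentArc[q] = -1;
            orphans.push_back(q);
          }
          double r = (myTree == SRC) ? res[a ^ 1] : res[a];
          if (r > EPS) pushActive(q);
        }
      }
    }
  }

  LogicalVector srcSide(nNodes, false);
  for (int v = 0; v < nNodes; ++v) srcSide[v] = (tree[v] == SRC);
  return List::create(Named("flow") = flow, Named("sourceSide") = srcSide);
}
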