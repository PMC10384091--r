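// Exact s-t max-flow / min-cut on the segmentation pixel graph.
// Dinic's algorithm with adjacency arrays; capacities are doubles.
// Nodes 1..n are pixels; a virtual source and sink are appended.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

namespace {

struct Dinic {
  int n;
  std::vector<int> to, nxt, head;
  std::vector<double> cap;

  explicit Dinic(int n_) : n(n_), head(n_, -1) {}

  void addArc(int u, int v, double c, double crev) {
    to.push_back(v); cap.push_back(c); nxt.push_back(head[u]);
    head[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(crev); nxt.push_back(head[v]);
    head[v] = (int)to.size() - 1;
  }

  std::vector<int> level, it;

  bool bfs(int s, int t) {
    level.assign(n, -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }

  // iterative DFS blocking flow
  double dfs(int s, int t) {
    std::vector<int> path;        // arc indices along the current path
    std::vector<int> node{s};
    double pushed = 0.0;
    while (true) {
      int u = node.back();
      if (u == t) {
        double f = std::numeric_limits<double>::infinity();
        for (int e : path) f = std::min(f, cap[e]);
        for (int e : path) { cap[e] -= f; cap[e ^ 1] += f; }
        pushed += f;
        // retreat to the first saturated arc
        size_t cut = 0;
        for (size_t i = 0; i < path.size(); ++i)
          if (cap[path[i]] <= 1e-12) { cut = i; break; }
        path.resize(cut);
        node.resize(cut + 1);
        continue;
      }
      int &e = it[u];
      bool advanced = false;
      for (; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] == level[u] + 1) {
          path.push_back(e);
          node.push_back(to[e]);
          advanced = true;
          break;
        }
      }
      if (!advanced) {
        level[u] = -1;  // dead end
        if (node.size() == 1) break;
        node.pop_back();
        path.pop_back();
      }
    }
    return pushed;
  }

  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      it = head;
      flow += dfs(s, t);
    }
    return flow;
  }
};

}  // namespace

// [[Rcpp::export(name = ".gridMaxflowCpp")]]
List gridMaxflowCpp(int n, IntegerMatrix edges, NumericVector w,
                    NumericVector capSrc, NumericVector capSnk) {
  int s = n, t = n + 1;  // 0-based internal ids
  Dinic d(n + 2);
  for (int i = 0; i < n; ++i) {
    if (capSrc[i] > 0) d.addArc(s, i, capSrc[i], 0.0);
    if (capSnk[i] > 0) d.addArc(i, t, capSnk[i], 0.0);
  }
  for (int k = 0; k < edges.nrow(); ++k) {
    // undirected pixel pair: equal residual capacity in both directions
    d.addArc(edges(k, 0) - 1, edges(k, 1) - 1, w[k], w[k]);
  }
  double flow = d.run(s, t);
  // source side of the min cut = residual-reachable from s
  LogicalVector src(n, false);
  std::vector<char> seen(n + 2, 0);
  std::queue<int> q;
  seen[s] = 1; q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int e = d.head[u]; e != -1; e = d.nxt[e]) {
      int v = d.to[e];
      if (d.cap[e] > 1e-12 && !seen[v]) { seen[v] = 1; q.push(v); }
    }
  }
  for (int i = 0; i < n; ++i) src[i] = seen[i] != 0;
  return List::create(_["flow"] = flow, _["source_side"] = src);
}
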