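#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow / min-cut for the optimal-surface graphs: static directed
// graph, double capacities. Returns the source-side min-cut membership for
// nodes 1..n (logical vector).

namespace {

struct Arc { int to; double cap; int rev; };

class Dinic {
public:
  Dinic(int n) : g(n), level(n), it(n) {}
  std::vector<std::vector<Arc>> g;
  std::vector<int> level, it;

  void add_edge(int u, int v, double c) {
    g[u].push_back({v, c, (int)g[v].size()});
    g[v].push_back({u, 0.0, (int)g[u].size() - 1});
  }
  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (const Arc& a : g[u])
        if (a.cap > 1e-12 && level[a.to] < 0) {
          level[a.to] = level[u] + 1;
          q.push(a.to);
        }
    }
    return level[t] >= 0;
  }
  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int& i = it[u]; i < (int)g[u].size(); ++i) {
      Arc& a = g[u][i];
      if (a.cap > 1e-12 && level[a.to] == level[u] + 1) {
        double d = dfs(a.to, t, std::min(f, a.cap));
        if (d > 0) {
          a.cap -= d;
          g[a.to][a.rev].cap += d;
          return d;
        }
      }
    }
    return 0.0;
  }
  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      std::fill(it.begin(), it.end(), 0);
      double f;
      while ((f = dfs(s, t, R_PosInf)) > 0) flow += f;
    }
    return flow;
  }
};

} // namespace

// [[Rcpp::export(name = ".mincut_cpp")]]
List mincut_cpp(int n_nodes, IntegerVector from, IntegerVector to,
                NumericVector cap, int source, int target) {
  // node ids are 1-based; source/target included in n_nodes
  Dinic d(n_nodes);
  const R_xlen_t m = from.size();
  for (int u = 0; u < n_nodes; ++u) d.g[u].reserve(8);
  for (R_xlen_t i = 0; i < m; ++i)
    d.add_edge(from[i] - 1, to[i] - 1, cap[i]);
  double flow = d.run(source - 1, target - 1);
  // source side of the cut = nodes reachable in the residual graph
  LogicalVector side(n_nodes, FALSE);
  std::queue<int> q;
  q.push(source - 1); side[source - 1] = TRUE;
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (const Arc& a : d.g[u])
      if (a.cap > 1e-12 && !side[a.to]) {
        side[a.to] = TRUE;
        q.push(a.to);
      }
  }
  return List::create(_["flow"] = flow, _["source_side"] = side);
}
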