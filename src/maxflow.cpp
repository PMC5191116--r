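// Exact s-t min-cut for the binary Potts smoothing energy via Dinic's
// max-flow algorithm. Nodes 1..n are points; node 0 is the source (label
// 1 side), node n+1 the sink. Each point carries one terminal arc with
// capacity |u0 - u1|; each neighbor-graph edge carries `penalty` in both
// directions.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>

using namespace Rcpp;

namespace {

struct Arc { int to; double cap; int rev; };

struct Dinic {
  std::vector<std::vector<Arc>> g;
  std::vector<int> level, iter;
  explicit Dinic(int n) : g(n), level(n), iter(n) {}

  void addEdge(int a, int b, double cab, double cba) {
    g[a].push_back({b, cab, (int)g[b].size()});
    g[b].push_back({a, cba, (int)g[a].size() - 1});
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (const Arc& a : g[u]) {
        if (a.cap > 1e-12 && level[a.to] < 0) {
          level[a.to] = level[u] + 1;
          q.push(a.to);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int& i = iter[u]; i < (int)g[u].size(); ++i) {
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
    return 0;
  }

  double maxflow(int s, int t) {
    double flow = 0;
    while (bfs(s, t)) {
      std::fill(iter.begin(), iter.end(), 0);
      double f;
      while ((f = dfs(s, t, std::numeric_limits<double>::infinity())) > 0) {
        flow += f;
      }
    }
    return flow;
  }

  // residual reachability from s = source side of the min cut
  void sourceSide(int s, std::vector<char>& inS) {
    std::fill(inS.begin(), inS.end(), 0);
    std::queue<int> q;
    inS[s] = 1;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (const Arc& a : g[u]) {
        if (a.cap > 1e-12 && !inS[a.to]) {
          inS[a.to] = 1;
          q.push(a.to);
        }
      }
    }
  }
};

}  // namespace

// edges: E x 2 (1-based point indices); fromS/toT: per-point terminal
// capacities (at most one of the two is positive per point). Returns
// 0/1 labels (1 = source side).
// [[Rcpp::export(name = ".cppMinCutPotts")]]
IntegerVector cpp_min_cut_potts(int n, const IntegerMatrix& edges,
                                double penalty, const NumericVector& fromS,
                                const NumericVector& toT) {
  const int s = 0, t = n + 1;
  Dinic din(n + 2);
  for (int i = 0; i < n; ++i) {
    if (fromS[i] > 0) din.addEdge(s, i + 1, fromS[i], 0.0);
    if (toT[i] > 0) din.addEdge(i + 1, t, toT[i], 0.0);
  }
  for (int e = 0; e < edges.nrow(); ++e) {
    din.addEdge(edges(e, 0), edges(e, 1), penalty, penalty);
  }
  din.maxflow(s, t);
  std::vector<char> inS(n + 2);
  din.sourceSide(s, inS);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = inS[i + 1] ? 1 : 0;
  return out;
}
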