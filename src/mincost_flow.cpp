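#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Min-cost max flow on an undirected graph by successive shortest
// augmenting paths (Dijkstra with Johnson potentials). Edge costs are
// -log(reliability) >= 0, so among all maximum flows this one maximizes
// the product of reliabilities over flow-carrying edges -- the flow whose
// path decomposition gives the best product-form reliability bound.
// Each augmentation pushes one unit; flow on an undirected edge is signed
// relative to its (from, to) orientation. Nodes are 0-based.
// [[Rcpp::export]]
List cpp_mincost_maxflow(int n_nodes, IntegerVector from, IntegerVector to,
                         NumericVector cap, NumericVector cost,
                         int source, int sink) {
  const int E = from.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> f(E, 0.0);
  // adjacency: node -> (edge id, direction)
  std::vector<std::vector<std::pair<int, int>>> adj(n_nodes);
  for (int e = 0; e < E; ++e) {
    adj[from[e]].push_back({e, +1});
    adj[to[e]].push_back({e, -1});
  }
  std::vector<double> h(n_nodes, 0.0), dist(n_nodes);
  std::vector<int> par_edge(n_nodes), par_dir(n_nodes);
  int value = 0;
  typedef std::pair<double, int> QN;
  while (true) {
    std::fill(dist.begin(), dist.end(), INF);
    dist[source] = 0.0;
    std::priority_queue<QN, std::vector<QN>, std::greater<QN>> pq;
    pq.push({0.0, source});
    while (!pq.empty()) {
      QN top = pq.top(); pq.pop();
      int u = top.second;
      if (top.first > dist[u] + 1e-12) continue;
      for (auto& ar : adj[u]) {
        int e = ar.first, dir = ar.second;
        double residual = cap[e] - dir * f[e];
        if (residual < 0.5) continue;
        double c = (dir * f[e] < -1e-9) ? -cost[e] : cost[e];
        int v = (dir > 0) ? to[e] : from[e];
        double rc = c + h[u] - h[v];
        if (rc < 0) rc = 0;  // guard float slack in reduced costs
        double nd = dist[u] + rc;
        if (nd + 1e-12 < dist[v]) {
          dist[v] = nd;
          par_edge[v] = e; par_dir[v] = dir;
          pq.push({nd, v});
        }
      }
    }
    if (!std::isfinite(dist[sink])) break;
    for (int v = 0; v < n_nodes; ++v)
      if (std::isfinite(dist[v])) h[v] += dist[v];
    for (int v = sink; v != source;) {
      int e = par_edge[v], dir = par_dir[v];
      f[e] += dir;
      v = (dir > 0) ? from[e] : to[e];
    }
    ++value;
  }
  return List::create(_["flow"] = NumericVector(f.begin(), f.end()),
                      _["value"] = value);
}
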