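#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find with path halving
static int find_root(std::vector<int>& p, int x) {
  while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
  return x;
}

// Exact two-terminal (multi-source) reliability by enumerating all 2^E
// edge operational states. Nodes are 0-based indices.
// [[Rcpp::export]]
double cpp_exact_reliability(IntegerVector from, IntegerVector to,
                             NumericVector prob, IntegerVector sources,
                             int sink, int n_nodes) {
  const int E = from.size();
  if (E > 30) stop("enumeration over 2^%d edge states is not feasible", E);
  const long long total = 1LL << E;
  double acc = 0.0;
  std::vector<int> parent(n_nodes);
  for (long long mask = 0; mask < total; ++mask) {
    double pr = 1.0;
    for (int e = 0; e < E; ++e)
      pr *= (mask >> e & 1LL) ? prob[e] : 1.0 - prob[e];
    if (pr <= 0.0) continue;
    for (int v = 0; v < n_nodes; ++v) parent[v] = v;
    for (int e = 0; e < E; ++e)
      if (mask >> e & 1LL) {
        int a = find_root(parent, from[e]), b = find_root(parent, to[e]);
        if (a != b) parent[a] = b;
      }
    const int rs = find_root(parent, sink);
    for (int i = 0; i < sources.size(); ++i)
      if (find_root(parent, sources[i]) == rs) { acc += pr; break; }
  }
  return acc;
}
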