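#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Brandes-style accumulation of betweenness and stress centrality on an
// undirected, unweighted simple graph. Betweenness is returned as the raw
// sum over unordered source-target pairs (normalisation happens in R);
// stress is the raw count of shortest paths through each node.
//
// Stress uses the path-count accumulation: with sigma_sv shortest-path
// counts from source s and tau_s(v) the number of shortest-path
// continuations below v in the BFS DAG (tau_s(v) = sum over successors w of
// (1 + tau_s(w))), the contribution of source s to stress(v) is
// sigma_sv * tau_s(v).

// [[Rcpp::export]]
List brandes_cpp(int n, IntegerVector from, IntegerVector to) {
  int m = from.size();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) { deg[from[e]]++; deg[to[e]]++; }
  std::vector<int> off(n + 1, 0);
  for (int v = 0; v < n; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(2 * (size_t)m);
  std::vector<int> cur(off.begin(), off.end() - 1);
  for (int e = 0; e < m; ++e) {
    adj[cur[from[e]]++] = to[e];
    adj[cur[to[e]]++] = from[e];
  }

  std::vector<double> bc(n, 0.0), stress(n, 0.0);
  std::vector<int> dist(n), stack_(n), queue_(n);
  std::vector<double> sigma(n), delta(n), tau(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(tau.begin(), tau.end(), 0.0);
    int qh = 0, qt = 0, sp = 0;
    dist[s] = 0; sigma[s] = 1.0;
    queue_[qt++] = s;
    while (qh < qt) {
      int v = queue_[qh++];
      stack_[sp++] = v;
      for (int i = off[v]; i < off[v + 1]; ++i) {
        int w = adj[i];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; queue_[qt++] = w; }
        if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
      }
    }
    while (sp > 0) {
      int w = stack_[--sp];
      for (int i = off[w]; i < off[w + 1]; ++i) {
        int v = adj[i];
        if (dist[v] == dist[w] - 1) {  // v is a predecessor of w
          delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
          tau[v] += 1.0 + tau[w];
        }
      }
      if (w != s) {
        bc[w] += delta[w];
        stress[w] += sigma[w] * tau[w];
      }
    }
  }
  for (int v = 0; v < n; ++v) { bc[v] /= 2.0; stress[v] /= 2.0; }
  return List::create(_["betweenness"] = NumericVector(bc.begin(), bc.end()),
                      _["stress"] = NumericVector(stress.begin(), stress.end()));
}
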