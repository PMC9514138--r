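#include <Rcpp.h>
#include <vector>
#include <queue>

// Shortest-path efficiencies on a binary undirected graph, via BFS from every
// node. Disconnected pairs contribute 0 (1/infinity). Adjacency is passed as
// a 0/1 integer matrix with zero diagonal.

static double pair_efficiency_sum(const std::vector<std::vector<int>>& nbrs,
                                  int n) {
  // sum over ordered pairs of 1/d(i,j); caller divides by n(n-1)
  double total = 0.0;
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      for (int v : nbrs[u]) {
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          q.push(v);
        }
      }
    }
    for (int t = 0; t < n; ++t)
      if (t != s && dist[t] > 0) total += 1.0 / dist[t];
  }
  return total;
}

static std::vector<std::vector<int>> adj_to_lists(
    const Rcpp::IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int>> nbrs(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nbrs[i].push_back(j);
  return nbrs;
}

// [[Rcpp::export]]
double global_efficiency_cpp(const Rcpp::IntegerMatrix& adj) {
  const int n = adj.nrow();
  if (n < 2) return 0.0;
  auto nbrs = adj_to_lists(adj);
  return pair_efficiency_sum(nbrs, n) / ((double)n * (n - 1));
}

// [[Rcpp::export]]
Rcpp::NumericVector local_efficiency_cpp(const Rcpp::IntegerMatrix& adj) {
  const int n = adj.nrow();
  Rcpp::NumericVector out(n);
  auto nbrs = adj_to_lists(adj);
  for (int i = 0; i < n; ++i) {
    const int k = (int)nbrs[i].size();
    if (k < 2) {
      out[i] = 0.0;
      continue;
    }
    // induced subgraph on the neighbours of i
    std::vector<int> pos(n, -1);
    for (int a = 0; a < k; ++a) pos[nbrs[i][a]] = a;
    std::vector<std::vector<int>> sub(k);
    for (int a = 0; a < k; ++a)
      for (int v : nbrs[nbrs[i][a]])
        if (pos[v] >= 0) sub[a].push_back(pos[v]);
    out[i] = pair_efficiency_sum(sub, k) / ((double)k * (k - 1));
  }
  return out;
}
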