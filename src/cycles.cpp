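#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smallest directed cycle through each requested node.
//
// For a node v, the smallest cycle through v is the shortest directed path
// v -> ... -> u over all in-neighbours u of v, closed by the edge u -> v.
// Breadth-first search from v gives shortest paths; neighbours are visited
// in ascending node order so the BFS tree (and hence the reconstructed
// path) is deterministic. Ties between candidate cycles of equal edge
// count are broken by smaller geometric perimeter, then by the
// lexicographically smallest node-id sequence.
//
// edges: m x 2 integer matrix, 1-based node indices (src, dst)
// coords: n x 3 positions (mm), used only for the perimeter tie-break
// targets: 1-based node indices to search from
// Returns a list (one element per target): integer vector of 1-based node
// indices (cycle stored open, starting at the target), or NULL if the
// target lies on no cycle.

static double edge_len(const NumericMatrix& xyz, int a, int b) {
  double dx = xyz(a, 0) - xyz(b, 0);
  double dy = xyz(a, 1) - xyz(b, 1);
  double dz = xyz(a, 2) - xyz(b, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
List smallest_cycles_cpp(int n, IntegerMatrix edges, NumericMatrix coords,
                         IntegerVector targets) {
  int m = edges.nrow();
  // CSR out-adjacency and in-adjacency, sorted for determinism
  std::vector<std::vector<int> > out_adj(n), in_adj(n);
  for (int e = 0; e < m; ++e) {
    int s = edges(e, 0) - 1, d = edges(e, 1) - 1;
    if (s == d) continue;
    out_adj[s].push_back(d);
    in_adj[d].push_back(s);
  }
  for (int i = 0; i < n; ++i) {
    std::sort(out_adj[i].begin(), out_adj[i].end());
    out_adj[i].erase(std::unique(out_adj[i].begin(), out_adj[i].end()),
                     out_adj[i].end());
    std::sort(in_adj[i].begin(), in_adj[i].end());
    in_adj[i].erase(std::unique(in_adj[i].begin(), in_adj[i].end()),
                    in_adj[i].end());
  }

  const int INF = -1;
  std::vector<int> dist(n), parent(n);
  List res(targets.size());

  for (int ti = 0; ti < targets.size(); ++ti) {
    int v = targets[ti] - 1;
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(parent.begin(), parent.end(), -1);
    dist[v] = 0;
    std::queue<int> q;
    q.push(v);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (size_t k = 0; k < out_adj[u].size(); ++k) {
        int w = out_adj[u][k];
        if (dist[w] == INF) {
          dist[w] = dist[u] + 1;
          parent[w] = u;
          q.push(w);
        }
      }
    }
    // candidate closing nodes: in-neighbours of v reachable from v
    int best_len = -1;
    double best_perim = 0.0;
    std::vector<int> best_path;
    for (size_t k = 0; k < in_adj[v].size(); ++k) {
      int u = in_adj[v][k];
      if (u == v || dist[u] == INF) continue;
      int clen = dist[u] + 1;
      if (best_len != -1 && clen > best_len) continue;
      // reconstruct path v -> ... -> u
      std::vector<int> path;
      for (int x = u; x != -1; x = parent[x]) path.push_back(x);
      std::reverse(path.begin(), path.end()); // starts at v, ends at u
      double perim = 0.0;
      for (size_t j = 0; j + 1 < path.size(); ++j)
        perim += edge_len(coords, path[j], path[j + 1]);
      perim += edge_len(coords, u, v);
      bool take = false;
      if (best_len == -1 || clen < best_len) {
        take = true;
      } else { // clen == best_len
        if (perim < best_perim - 1e-9) {
          take = true;
        } else if (std::fabs(perim - best_perim) <= 1e-9) {
          take = std::lexicographical_compare(path.begin(), path.end(),
                                              best_path.begin(),
                                              best_path.end());
        }
      }
      if (take) {
        best_len = clen;
        best_perim = perim;
        best_path = path;
      }
    }
    if (best_len == -1) {
      res[ti] = R_NilValue;
    } else {
      IntegerVector out(best_path.size());
      for (size_t j = 0; j < best_path.size(); ++j) out[j] = best_path[j] + 1;
      res[ti] = out;
    }
  }
  return res;
}
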