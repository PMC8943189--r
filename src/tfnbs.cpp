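#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression; arrays are reset per threshold level.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Threshold-free enhancement of an edge-wise statistic map.
//
// For thresholds h_k = k * dh, k = 1..n_steps with dh = max(t)/n_steps, each
// edge accumulates extent(h_k)^E * h_k^H * dh over the thresholds it survives
// (t >= h_k). Extent is either the edge count of the suprathreshold connected
// component containing the edge ("component") or the number of suprathreshold
// edges incident to either endpoint, the edge itself included ("incident").
//
// tvec / ei / ej: statistic and 0-based endpoints of candidate edges (t > 0).
// Returns per-edge scores in the same order.
// [[Rcpp::export(name = ".tfnbs_score_edges")]]
NumericVector tfnbs_score_edges(NumericVector tvec, IntegerVector ei,
                                IntegerVector ej, int n_nodes,
                                double expE, double expH, int n_steps,
                                bool component_extent) {
  const int m = tvec.size();
  NumericVector score(m);
  if (m == 0) return score;
  double tmax = 0.0;
  for (int e = 0; e < m; ++e) {
    if (tvec[e] < 0) stop("negative statistic; truncate before scoring");
    if (tvec[e] > tmax) tmax = tvec[e];
  }
  if (tmax <= 0.0) return score;  // all-zero map: dh undefined, scores zero
  const double dh = tmax / n_steps;

  std::vector<int> parent(n_nodes), comp_edges(n_nodes), deg(n_nodes);
  for (int k = 1; k <= n_steps; ++k) {
    const double h = k * dh;
    // survival test with an absolute guard so the top bin (h == max t up
    // to rounding) is never lost to 1-ulp float noise
    const double hcmp = h - tmax * 1e-12;
    const double hterm = std::pow(h, expH) * dh;
    if (component_extent) {
      for (int v = 0; v < n_nodes; ++v) { parent[v] = v; comp_edges[v] = 0; }
      for (int e = 0; e < m; ++e) {
        if (tvec[e] >= hcmp) {
          int a = uf_find(parent, ei[e]);
          int b = uf_find(parent, ej[e]);
          if (a != b) parent[a] = b;
        }
      }
      for (int e = 0; e < m; ++e) {
        if (tvec[e] >= hcmp) comp_edges[uf_find(parent, ei[e])]++;
      }
      for (int e = 0; e < m; ++e) {
        if (tvec[e] >= hcmp) {
          int ext = comp_edges[uf_find(parent, ei[e])];
          score[e] += std::pow((double)ext, expE) * hterm;
        }
      }
    } else {
      std::fill(deg.begin(), deg.end(), 0);
      for (int e = 0; e < m; ++e) {
        if (tvec[e] >= hcmp) { deg[ei[e]]++; deg[ej[e]]++; }
      }
      for (int e = 0; e < m; ++e) {
        if (tvec[e] >= hcmp) {
          int ext = deg[ei[e]] + deg[ej[e]] - 1;  // shared edge counted once
          score[e] += std::pow((double)ext, expE) * hterm;
        }
      }
    }
  }
  return score;
}
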