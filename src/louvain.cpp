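#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy Louvain-style optimisation of a dense symmetric modularity matrix:
// local node moves maximising the within-community sum of B, followed by
// community aggregation, repeated until no further improvement. The caller
// supplies the (0-based) node visiting order for the first level; deeper
// levels use sequential order, so all stochasticity lives in `order`.
// Diagonal entries travel with their node and are excluded from move gains
// but included in the reported quality Q.
// [[Rcpp::export]]
List louvain_dense(NumericMatrix B, IntegerVector order) {
  const int n = B.nrow();
  std::vector<double> M(B.begin(), B.end()); // column-major, symmetric
  std::vector<int> final_label(n);
  for (int i = 0; i < n; ++i) final_label[i] = i;

  int n_cur = n;
  bool first_level = true;
  std::vector<int> comm;

  for (;;) {
    comm.assign(n_cur, 0);
    for (int i = 0; i < n_cur; ++i) comm[i] = i;
    std::vector<double> conn(n_cur);
    bool any_move = false, improved = true;
    while (improved) {
      improved = false;
      for (int oi = 0; oi < n_cur; ++oi) {
        const int i = first_level ? order[oi] : oi;
        std::fill(conn.begin(), conn.end(), 0.0);
        const double* col = &M[(size_t)i * n_cur];
        for (int j = 0; j < n_cur; ++j) conn[comm[j]] += col[j];
        conn[comm[i]] -= col[i]; // exclude self-loop
        int best = comm[i];
        double bestv = conn[best];
        for (int c = 0; c < n_cur; ++c) {
          if (conn[c] > bestv + 1e-12) { bestv = conn[c]; best = c; }
        }
        if (best != comm[i]) { comm[i] = best; improved = true; any_move = true; }
      }
    }
    // compress community ids
    std::vector<int> remap(n_cur, -1);
    int k = 0;
    for (int i = 0; i < n_cur; ++i) {
      if (remap[comm[i]] < 0) remap[comm[i]] = k++;
      comm[i] = remap[comm[i]];
    }
    for (int v = 0; v < n; ++v) final_label[v] = comm[final_label[v]];
    if (!any_move || k == n_cur) break;
    // aggregate M into k x k community matrix
    std::vector<double> M2((size_t)k * k, 0.0);
    for (int i = 0; i < n_cur; ++i) {
      const double* col = &M[(size_t)i * n_cur];
      for (int j = 0; j < n_cur; ++j) {
        M2[(size_t)comm[i] * k + comm[j]] += col[j];
      }
    }
    M.swap(M2);
    n_cur = k;
    first_level = false;
  }

  double Q = 0.0;
  for (int i = 0; i < n_cur; ++i) {
    const double* col = &M[(size_t)i * n_cur];
    for (int j = 0; j < n_cur; ++j) {
      if (comm[i] == comm[j]) Q += col[j];
    }
  }

  IntegerVector lab(n);
  for (int v = 0; v < n; ++v) lab[v] = final_label[v] + 1;
  return List::create(_["labels"] = lab, _["Q"] = Q);
}
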