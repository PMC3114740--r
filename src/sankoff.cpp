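#include <Rcpp.h>
using namespace Rcpp;

// Generalized Sankoff dynamic programme over a rooted tree.
//
// Nodes follow the ape convention: tips 1..n_tip, internals n_tip+1 .. n_node.
// `edge` must be in postorder (every edge below a node precedes the node's
// own incoming edge). Tip uncertainty (polymorphism, missing data) enters
// through per-state tip costs of 0 (allowed) or BIG (excluded), so no special
// casing is needed in the recursion; infinite transition costs (irreversible
// characters) are encoded as BIG at the R level, and any total at or above
// BIG/2 signals an impossible assignment.
//
// To keep per-tree call overhead negligible during search, all characters are
// passed as two flat arrays with offsets: tip_flat holds each character's
// S x m tip-cost matrix (column-major over the *matrix* taxa) and cost_flat
// each S x S transformation-cost matrix. tipmap (1-based, length n_tip) sends
// a tree tip to its taxon column, so one precomputed layout serves every
// candidate tree.

// [[Rcpp::export]]
NumericVector sankoff_lengths_cpp(IntegerMatrix edge, int n_tip, int n_node,
                                  IntegerVector S_per_char,
                                  NumericVector tip_flat, IntegerVector tip_off,
                                  NumericVector cost_flat, IntegerVector cost_off,
                                  IntegerVector tipmap) {
  const int n_char = S_per_char.size();
  const int n_edge = edge.nrow();
  const double BIG = 1e12;
  NumericVector out(n_char);

  const int *ep = edge.begin();            // column-major: parents then children
  const int *ec = ep + n_edge;
  const double *tf = tip_flat.begin();
  const double *cf = cost_flat.begin();
  const int *tmap = tipmap.begin();

  int max_S = 0;
  for (int c = 0; c < n_char; ++c) if (S_per_char[c] > max_S) max_S = S_per_char[c];
  std::vector<double> acc((size_t)(n_node - n_tip) * max_S);

  for (int c = 0; c < n_char; ++c) {
    const int S = S_per_char[c];
    const double *tc = tf + tip_off[c];    // S x m, column-major
    const double *cm = cf + cost_off[c];   // S x S, column-major: cm[s + S*t]
    std::fill(acc.begin(), acc.begin() + (size_t)(n_node - n_tip) * S, 0.0);

    for (int e = 0; e < n_edge; ++e) {
      const int parent = ep[e] - 1;
      const int child  = ec[e] - 1;
      const double *child_cost = (child < n_tip)
        ? tc + (size_t)S * (tmap[child] - 1)
        : &acc[(size_t)(child - n_tip) * S];
      double *pc = &acc[(size_t)(parent - n_tip) * S];
      for (int s = 0; s < S; ++s) {
        double best = BIG;
        for (int t = 0; t < S; ++t) {
          const double v = child_cost[t] + cm[s + S * t];
          if (v < best) best = v;
        }
        pc[s] += best;
      }
    }

    const int root = ep[n_edge - 1] - 1;
    const double *rc = &acc[(size_t)(root - n_tip) * S];
    double best = rc[0];
    for (int s = 1; s < S; ++s) if (rc[s] < best) best = rc[s];
    out[c] = best;
  }
  return out;
}

// Down-pass cost matrix for a single character: (n_node x S), rows for tips
// filled with their tip costs. Used by MPR backtracking in R.

// [[Rcpp::export]]
NumericMatrix sankoff_node_costs_cpp(IntegerMatrix edge, int n_tip, int n_node,
                                     NumericMatrix tipcost, NumericMatrix costmat,
                                     IntegerVector tipmap) {
  const int n_edge = edge.nrow();
  const int S = costmat.nrow();
  const double BIG = 1e12;
  NumericMatrix node_cost(n_node, S);
  for (int i = 0; i < n_tip; ++i)
    for (int s = 0; s < S; ++s) node_cost(i, s) = tipcost(s, tipmap[i] - 1);

  for (int e = 0; e < n_edge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child  = edge(e, 1) - 1;
    for (int s = 0; s < S; ++s) {
      double best = BIG;
      for (int t = 0; t < S; ++t) {
        const double v = node_cost(child, t) + costmat(s, t);
        if (v < best) best = v;
      }
      node_cost(parent, s) += best;
    }
  }
  return node_cost;
}
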