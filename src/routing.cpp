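#include <Rcpp.h>
using namespace Rcpp;

// Route every row of X through a set of flattened rank-pair trees.
//
// Nodes of all trees live in shared 1-based arrays: var_i/var_j give the
// gene pair of an internal node (var_i == 0 marks a terminal), left/right
// the child node ids.  A sample goes left iff x[var_i] <= x[var_j] (ties
// left by convention).  Returns the terminal node id for each (sample, tree).
// [[Rcpp::export]]
IntegerMatrix route_forest_cpp(IntegerVector var_i, IntegerVector var_j,
                               IntegerVector left, IntegerVector right,
                               NumericMatrix X, IntegerVector roots) {
  const int n = X.nrow(), M = roots.size();
  IntegerMatrix out(n, M);
  for (int m = 0; m < M; ++m) {
    const int root = roots[m] - 1;
    for (int s = 0; s < n; ++s) {
      int node = root;
      while (var_i[node] > 0) {
        const double xi = X(s, var_i[node] - 1);
        const double xj = X(s, var_j[node] - 1);
        node = (xi <= xj) ? left[node] - 1 : right[node] - 1;
      }
      out(s, m) = node + 1;
    }
  }
  return out;
}
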