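#include <Rcpp.h>
using namespace Rcpp;

// Data-processing-inequality pruning over a symmetric mutual-information
// matrix: edge (i,j) is removed when some third gene k has
// min(MI_ik, MI_jk) > MI_ij + eps, i.e. (i,j) is the strictly weakest edge
// of the triangle (up to the tolerance). The weakest edge is only ever
// removed, never the strongest.
// [[Rcpp::export]]
NumericMatrix dpi_prune_cpp(NumericMatrix mi, double eps) {
  int p = mi.nrow();
  NumericMatrix out = clone(mi);
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double mij = mi(i, j);
      if (mij <= 0.0) continue;
      for (int k = 0; k < p; ++k) {
        if (k == i || k == j) continue;
        double mik = mi(i, k);
        double mjk = mi(j, k);
        double m = mik < mjk ? mik : mjk;
        if (mij < m - eps) {
          out(i, j) = 0.0;
          out(j, i) = 0.0;
          break;
        }
      }
    }
  }
  return out;
}
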