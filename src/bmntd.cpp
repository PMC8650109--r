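#include <Rcpp.h>
using namespace Rcpp;

// Pairwise abundance-weighted betaMNTD for all sample pairs.
//
// dm     : S x S patristic distance matrix (taxon order fixed)
// relab  : n x S relative-abundance matrix, rows = samples, columns aligned
//          with dm. Entries > 0 mark taxa present in a sample.
// perm   : length-S permutation (0-based) of taxon identities. The identity
//          permutation gives the observed statistic; a random permutation
//          gives one null replicate (equivalent to shuffling tip labels
//          across the phylogeny).
//
// For each sample b we precompute minvec_b[i] = min_{j present in b}
// dm[perm[i], perm[j]] for every taxon i, so each pair costs O(S) after an
// O(S * richness) scan per sample.
// [[Rcpp::export]]
NumericMatrix bmntd_pairwise_cpp(const NumericMatrix& dm,
                                 const NumericMatrix& relab,
                                 const IntegerVector& perm) {
  const int n = relab.nrow();
  const int S = relab.ncol();
  if (dm.nrow() != S || dm.ncol() != S)
    stop("distance matrix dimension does not match taxon count");
  if (perm.size() != S)
    stop("permutation length does not match taxon count");

  // presence lists
  std::vector< std::vector<int> > present(n);
  for (int s = 0; s < n; ++s) {
    present[s].reserve(S);
    for (int j = 0; j < S; ++j)
      if (relab(s, j) > 0) present[s].push_back(j);
    if (present[s].empty())
      stop("sample %d has no taxa with positive abundance", s + 1);
  }

  // minmat(i, b) = distance from taxon i to its nearest taxon present in b
  NumericMatrix minmat(S, n);
  for (int b = 0; b < n; ++b) {
    const std::vector<int>& pb = present[b];
    for (int i = 0; i < S; ++i) {
      double m = R_PosInf;
      const int pi = perm[i];
      for (size_t k = 0; k < pb.size(); ++k) {
        const double d = dm(pi, perm[pb[k]]);
        if (d < m) m = d;
      }
      minmat(i, b) = m;
    }
  }

  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double acc = 0.0;
      const std::vector<int>& pa = present[a];
      const std::vector<int>& pb = present[b];
      for (size_t k = 0; k < pa.size(); ++k)
        acc += relab(a, pa[k]) * minmat(pa[k], b);
      for (size_t k = 0; k < pb.size(); ++k)
        acc += relab(b, pb[k]) * minmat(pb[k], a);
      acc *= 0.5;
      out(a, b) = acc;
      out(b, a) = acc;
    }
  }
  return out;
}
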