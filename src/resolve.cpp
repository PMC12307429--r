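#include <Rcpp.h>
using namespace Rcpp;

// Number of accession pairs resolved by a locus subset. D is the
// pair-by-candidate difference matrix (rows = accession pairs, TRUE where
// the pair's dosages differ at that candidate); cols holds 1-based column
// indices of the selected candidates. Early-exits per pair.
// [[Rcpp::export]]
int count_resolved_pairs_cpp(const LogicalMatrix& D,
                             const IntegerVector& cols) {
  const int n = D.nrow(), k = cols.size();
  int cnt = 0;
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < k; ++j) {
      if (D(r, cols[j] - 1)) { ++cnt; break; }
    }
  }
  return cnt;
}
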