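#include <Rcpp.h>
using namespace Rcpp;

// weighted tabulate: sums w over 1-based bin indices
// [[Rcpp::export]]
NumericVector cpp_weighted_bincount(IntegerVector idx, NumericVector w,
                                    int nbins, int repeat_w) {
  NumericVector out(nbins);
  const int n = idx.size(), nw = w.size();
  for (int i = 0; i < n; ++i) {
    const int b = idx[i];
    if (b >= 1 && b <= nbins) out[b - 1] += w[repeat_w ? (i % nw) : i];
  }
  return out;
}
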