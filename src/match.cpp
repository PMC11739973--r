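#include <Rcpp.h>
using namespace Rcpp;

// Greedy fragment matching: both vectors ascending; each observed peak is
// consumed at most once, ladder ions are visited in ascending m/z and take
// the lowest-m/z unused peak within tolerance.
// [[Rcpp::export]]
int ie_match_count(NumericVector ladder, NumericVector peaks, double tol) {
  int i = 0, j = 0, m = 0;
  const int nl = ladder.size(), np = peaks.size();
  while (i < nl && j < np) {
    if (peaks[j] < ladder[i] - tol) {
      ++j;
    } else if (peaks[j] > ladder[i] + tol) {
      ++i;
    } else {
      ++m; ++i; ++j;
    }
  }
  return m;
}

// Matched-fragment counts for one spectrum against many candidate ladders.
// [[Rcpp::export]]
IntegerVector ie_score_spectrum(NumericVector peaks, List ladders, double tol) {
  const int n = ladders.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    NumericVector lad = ladders[k];
    out[k] = ie_match_count(lad, peaks, tol);
  }
  return out;
}
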