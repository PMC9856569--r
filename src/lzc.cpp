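#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv 1976 exhaustive-history phrase count (Kaspar-Schuster scheme).
// s is a binary (or small-alphabet) integer sequence; returns the number of
// phrases in the exhaustive production history of s.
// [[Rcpp::export]]
int lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n < 1) stop("empty sequence");
  if (n == 1) return 1;
  int c = 1;       // phrase count (first symbol is always one phrase)
  int l = 1;       // start (0-based) of the phrase being built
  int i = 0;       // candidate match start in the history
  int k = 1;       // current match length
  int kmax = 1;    // longest match found for this phrase
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {           // no longer match anywhere in the history
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
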