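// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Tabular-method recursion for the numerator relationship matrix of one
// (connected) pedigree component. fi/mi are 1-based positions of the
// parents within the component (0 = unknown), in an order where every
// parent precedes its offspring.
// [[Rcpp::export]]
arma::mat tabular_A(const arma::ivec& fi, const arma::ivec& mi) {
  const arma::uword n = fi.n_elem;
  arma::mat A(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    const int f = fi[i] - 1, m = mi[i] - 1;
    for (arma::uword j = 0; j < i; ++j) {
      double v = 0.0;
      if (f >= 0) v += A(j, f);
      if (m >= 0) v += A(j, m);
      v *= 0.5;
      A(i, j) = v;
      A(j, i) = v;
    }
    A(i, i) = 1.0 + ((f >= 0 && m >= 0) ? 0.5 * A(f, m) : 0.0);
  }
  return A;
}
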