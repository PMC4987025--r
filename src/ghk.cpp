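// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Marginal deviance of the probit threshold model: -2 log P(observed
// category vector) per parameter draw, with ALL random effects and the
// residual integrated out, so the deviance depends only on (b, sigma,
// cutpoints). Each family's orthant probability under its marginal
// covariance V_b = sum_c sigma2_c K_cb + sigma2_e I is estimated by the
// GHK sequential-conditioning sampler. A caller-supplied uniform deviate
// matrix is reused across draws and across competing models (common
// random numbers), so DIC differences between models are not dominated
// by simulation noise.
//
// blocks: as in gibbs_ordinal_cpp (only idx and K are used here).
// U:      nrep x n matrix of uniforms in (0,1).
// [[Rcpp::export]]
arma::vec ghk_deviance_cpp(const arma::ivec& ycat, const arma::mat& X,
                           const List& blocks, int ncomp,
                           const arma::vec& cut,
                           const arma::mat& bdraws,
                           const arma::mat& sigdraws,
                           const arma::vec& resdraws,
                           const arma::mat& U) {
  const int nb = blocks.size();
  const int nd = bdraws.n_rows;
  const int nrep = U.n_rows;

  std::vector<arma::uvec> idxs(nb);
  std::vector<std::vector<arma::mat> > Kb(nb);
  std::vector<arma::mat> Xb(nb);
  for (int b = 0; b < nb; ++b) {
    List blk = blocks[b];
    idxs[b] = as<arma::uvec>(blk["idx"]) - 1;
    List Kc = blk["K"];
    for (int c = 0; c < ncomp; ++c)
      Kb[b].push_back(as<arma::mat>(Kc[c]));
    Xb[b] = X.rows(idxs[b]);
  }

  arma::vec dev(nd, arma::fill::zeros);
  for (int d = 0; d < nd; ++d) {
    arma::vec bcoef = bdraws.row(d).t();
    double s2e = resdraws[d];
    for (int b = 0; b < nb; ++b) {
      const arma::uword m = idxs[b].n_elem;
      arma::mat V(m, m, arma::fill::eye);
      V *= s2e;
      for (int c = 0; c < ncomp; ++c)
        V += sigdraws(d, c) * Kb[b][c];
      arma::mat L = arma::chol(V, "lower");
      arma::vec mu = Xb[b] * bcoef;
      // GHK with antithetic reuse of the supplied uniforms
      double psum = 0.0;
      arma::vec z(m);
      for (int r = 0; r < nrep; ++r) {
        double logp = 0.0;
        for (arma::uword i = 0; i < m; ++i) {
          int cat = ycat[idxs[b][i]];
          double part = 0.0;
          for (arma::uword j = 0; j < i; ++j) part += L(i, j) * z[j];
          double lo = (cut[cat] == R_NegInf) ? 0.0 :
            R::pnorm((cut[cat] - mu[i] - part) / L(i, i), 0.0, 1.0, 1, 0);
          double hi = (cut[cat + 1] == R_PosInf) ? 1.0 :
            R::pnorm((cut[cat + 1] - mu[i] - part) / L(i, i),
                     0.0, 1.0, 1, 0);
          double w = std::max(hi - lo, 1e-300);
          logp += std::log(w);
          double u = U(r, idxs[b][i]);
          z[i] = R::qnorm(lo + u * w, 0.0, 1.0, 1, 0);
          if (!R_FINITE(z[i])) z[i] = 0.0;
        }
        psum += std::exp(logp);
      }
      dev[d] += -2.0 * std::log(std::max(psum / nrep, 1e-300));
    }
  }
  return dev;
}
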