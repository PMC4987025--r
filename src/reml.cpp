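// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One evaluation of the restricted log-likelihood, its score, and the
// average-information matrix for a variance model linear in its
// parameters, V = sum_k theta_k G_k, where V is block diagonal over the
// connected components ("blocks") of the combined covariance pattern.
//
// blocks:  list of 1-based index vectors into y / rows of X
// Gpack:   list (one per parameter) of lists (one per block) of dense
//          m_b x m_b matrices holding that parameter's block of G_k
//
// Returns logL (restricted, up to a constant), score, AI matrix, GLS
// fixed-effect estimates with their covariance, y'Py, and tr(P G_k).
// [[Rcpp::export]]
List reml_eval(const arma::vec& theta, const List& blocks,
               const arma::vec& y, const arma::mat& X, const List& Gpack) {
  const int nb = blocks.size();
  const int np = theta.n_elem;
  const int p = X.n_cols;

  std::vector<arma::mat> Vinvs(nb), ViXs(nb);
  std::vector<arma::vec> Viys(nb);
  std::vector<arma::uvec> idxs(nb);

  double logdetV = 0.0;
  arma::mat XtViX(p, p, arma::fill::zeros);
  arma::vec XtViy(p, arma::fill::zeros);
  arma::vec trViG(np, arma::fill::zeros);
  std::vector<arma::mat> W(np, arma::mat(p, p, arma::fill::zeros));

  for (int b = 0; b < nb; ++b) {
    arma::uvec idx = as<arma::uvec>(blocks[b]) - 1;
    idxs[b] = idx;
    const arma::uword m = idx.n_elem;
    arma::mat Vb(m, m, arma::fill::zeros);
    for (int k = 0; k < np; ++k) {
      List Gk = Gpack[k];
      arma::mat Gkb = as<arma::mat>(Gk[b]);
      Vb += theta[k] * Gkb;
    }
    arma::mat L;
    if (!arma::chol(L, Vb, "lower"))
      return List::create(_["ok"] = false);
    logdetV += 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat Vinv = arma::inv_sympd(Vb);
    arma::vec yb = y.elem(idx);
    arma::mat Xb = X.rows(idx);
    arma::vec Viy = Vinv * yb;
    arma::mat ViX = Vinv * Xb;
    XtViX += Xb.t() * ViX;
    XtViy += Xb.t() * Viy;
    for (int k = 0; k < np; ++k) {
      List Gk = Gpack[k];
      arma::mat Gkb = as<arma::mat>(Gk[b]);
      trViG[k] += arma::accu(Vinv % Gkb);
      W[k] += ViX.t() * Gkb * ViX;
    }
    Vinvs[b] = std::move(Vinv);
    ViXs[b] = std::move(ViX);
    Viys[b] = std::move(Viy);
  }

  arma::mat B;
  if (!arma::inv_sympd(B, XtViX))
    return List::create(_["ok"] = false, _["singular_X"] = true);
  double sign, logdetXtViX;
  arma::log_det(logdetXtViX, sign, XtViX);
  arma::vec beta = B * XtViy;

  double yPy = 0.0;
  arma::vec q(np, arma::fill::zeros);       // y' P G_k P y
  arma::mat M(np, np, arma::fill::zeros);   // s_k' Vinv s_l
  arma::mat T(p, np, arma::fill::zeros);    // (ViX)' s_k

  for (int b = 0; b < nb; ++b) {
    const arma::uvec& idx = idxs[b];
    const arma::uword m = idx.n_elem;
    arma::vec r = Viys[b] - ViXs[b] * beta;   // (P y) on this block
    yPy += arma::dot(y.elem(idx), r);
    arma::mat S(m, np);
    for (int k = 0; k < np; ++k) {
      List Gk = Gpack[k];
      arma::mat Gkb = as<arma::mat>(Gk[b]);
      S.col(k) = Gkb * r;
    }
    q += S.t() * r;
    arma::mat U = Vinvs[b] * S;
    M += S.t() * U;
    T += ViXs[b].t() * S;
  }

  arma::vec trPG(np);
  for (int k = 0; k < np; ++k)
    trPG[k] = trViG[k] - arma::trace(B * W[k]);

  double logL = -0.5 * (logdetV + logdetXtViX + yPy);
  arma::vec score = -0.5 * (trPG - q);
  arma::mat AI = 0.5 * (M - T.t() * B * T);

  return List::create(_["ok"] = true, _["logL"] = logL,
                      _["score"] = score, _["AI"] = AI,
                      _["beta"] = beta, _["beta_cov"] = B,
                      _["yPy"] = yPy, _["trPG"] = trPG, _["q"] = q);
}
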