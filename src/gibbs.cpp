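// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Truncated standard-normal draw (mean mu, sd sd) via inversion; adequate
// for the moderate truncation regions of threshold models at cohort scale.
static inline double rtruncnorm1(double mu, double sd, double lo, double hi) {
  double a = (lo == R_NegInf) ? 0.0 : R::pnorm((lo - mu) / sd, 0.0, 1.0, 1, 0);
  double b = (hi == R_PosInf) ? 1.0 : R::pnorm((hi - mu) / sd, 0.0, 1.0, 1, 0);
  if (b - a < 1e-12) { // numerically degenerate region: clamp to boundary
    double edge = (a > 0.5) ? lo : hi;
    if (!R_FINITE(edge)) edge = mu;
    return edge;
  }
  double u = R::runif(a + 1e-12, b - 1e-12);
  return mu + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
}

// Partially collapsed Gibbs sampler for a probit threshold (liability)
// model with covariance-structured random effects, block diagonal over
// independent families:
//
//   liability  y* = X b + sum_c Z_c u_c + e,  e ~ N(0, sigma2_e),
//   u_c ~ N(0, sigma2_c Q_c^{-1}),
//   observed category j  <=>  y* in (cut_j, cut_{j+1}).
//
// Identification: binary traits fix the threshold at 0 and the residual
// variance at 1; ordinal traits fix all cutpoints (supplied by the
// caller at observed-frequency normal quantiles) and free the residual
// variance, avoiding the notoriously slow random walk of sampled
// cutpoints.
//
// The latent liabilities and the fixed effects are updated with the
// random effects integrated out (per-family marginal covariance
// V_b = sum_c sigma2_c Z_c Q_c^{-1} Z_c' + I), which decouples the
// liabilities from the individual-level genetic effects and removes the
// slow random-walk mixing of the centred sampler; u is then redrawn
// exactly from its full conditional and the variances from their
// inverse-chi-squared conditionals.
//
// DIC focus: the recorded deviance conditions on the fixed effects and
// the SHARED random effects only (genetic effects, groups of size >= 2).
// Purely private effects -- the singleton blocks of a group-share
// structure -- are integrated out analytically, entering the deviance
// through an inflated per-observation residual variance instead. This
// keeps DIC from rewarding models that merely add a private noise
// channel per individual.
//
// blocks: list with elements per family block:
//   idx  1-based observation indices (length m)
//   Z    m x M incidence over all random effects of the block, columns
//        grouped by component
//   Q    list of per-component prior precision matrices (q_c x q_c)
//   K    list of per-component m x m covariances Z_c Q_c^{-1} Z_c'
//   qs   integer vector of per-component effect counts q_c
//   shared  logical mask over the M columns: effect is shared (kept in
//           the deviance linear predictor)
// sing: n x ncomp indicator, 1 when the observation is a singleton
//       member of that component (its variance joins the residual in
//       the deviance)
// [[Rcpp::export]]
List gibbs_ordinal_cpp(const arma::ivec& ycat, int K, const arma::mat& X,
                       const List& blocks, const arma::mat& sing,
                       int ncomp, const arma::vec& comp_q_total,
                       double prior_df, double prior_scale,
                       double prior_df_resid, double prior_scale_resid,
                       const arma::vec& cut_fixed, bool free_resid,
                       int niter, int burnin, int thin,
                       const arma::vec& sigma_start) {
  const int n = ycat.n_elem;
  const int p = X.n_cols;
  const int nb = blocks.size();

  std::vector<arma::uvec> idxs(nb);
  std::vector<arma::mat> Zs(nb), Zsh(nb), Xb(nb);
  std::vector<std::vector<arma::mat> > Qs(nb), Kb(nb);
  std::vector<arma::ivec> qss(nb);
  std::vector<arma::uvec> shared_cols(nb);
  for (int b = 0; b < nb; ++b) {
    List blk = blocks[b];
    idxs[b] = as<arma::uvec>(blk["idx"]) - 1;
    Zs[b] = as<arma::mat>(blk["Z"]);
    qss[b] = as<arma::ivec>(blk["qs"]);
    List Qb = blk["Q"], Kc = blk["K"];
    for (int c = 0; c < ncomp; ++c) {
      Qs[b].push_back(as<arma::mat>(Qb[c]));
      Kb[b].push_back(as<arma::mat>(Kc[c]));
    }
    Xb[b] = X.rows(idxs[b]);
    arma::uvec sh = arma::find(as<arma::uvec>(blk["shared"]) > 0);
    shared_cols[b] = sh;
    Zsh[b] = Zs[b].cols(sh);
  }
  // preallocated per-block work buffers (dimensions never change)
  std::vector<arma::mat> Vw(nb), Pw(nb), LTw(nb), PXw(nb), Pu(nb);
  std::vector<arma::vec> muw(nb), ybw(nb), rhsw(nb), zw(nb), uw(nb);
  for (int b = 0; b < nb; ++b) {
    const arma::uword m = idxs[b].n_elem, M = Zs[b].n_cols;
    Vw[b].set_size(m, m); Pw[b].set_size(m, m);
    PXw[b].set_size(m, X.n_cols);
    Pu[b].set_size(M, M); LTw[b].set_size(M, M);
    muw[b].set_size(m); ybw[b].set_size(m);
    rhsw[b].set_size(M); zw[b].set_size(M); uw[b].set_size(M);
  }
  std::vector<arma::mat> ZtZ(nb);
  for (int b = 0; b < nb; ++b) ZtZ[b] = Zs[b].t() * Zs[b];

  arma::vec sigma2 = sigma_start;
  double sigma2e = 1.0;
  arma::vec bcoef(p, arma::fill::zeros);
  std::vector<arma::vec> us(nb);
  for (int b = 0; b < nb; ++b)
    us[b] = arma::vec(Zs[b].n_cols, arma::fill::zeros);
  arma::vec cut = cut_fixed; // length K + 1, cut[0] = -Inf, cut[K] = +Inf

  arma::vec ystar(n, arma::fill::zeros), eta(n, arma::fill::zeros);

  const int nsave = (niter - burnin) / thin;
  arma::mat sigma_trace(nsave, ncomp);
  arma::vec resid_trace(nsave);
  arma::mat b_trace(nsave, p);
  arma::vec dev_trace(nsave);
  arma::vec mean_eta(n, arma::fill::zeros);
  arma::vec mean_vi(n, arma::fill::zeros);
  int isave = 0;

  for (int it = 0; it < niter; ++it) {
    // per-family marginal precision of y* given (b, sigma)
    arma::mat XtViX(p, p, arma::fill::zeros);
    arma::vec XtViy(p, arma::fill::zeros);
    for (int b = 0; b < nb; ++b) {
      const arma::uword m = idxs[b].n_elem;
      arma::mat& V = Vw[b];
      V.zeros();
      V.diag().fill(sigma2e);
      for (int c = 0; c < ncomp; ++c)
        V += sigma2[c] * Kb[b][c];
      arma::mat& P = Pw[b];
      if (!arma::inv_sympd(P, V)) P = arma::pinv(V);
      // 1. single-site sweep of the truncated liabilities under the
      //    marginal covariance (random effects integrated out)
      arma::vec& mu = muw[b];
      mu = Xb[b] * bcoef;
      arma::vec& yb = ybw[b];
      for (arma::uword i = 0; i < m; ++i) yb[i] = ystar[idxs[b][i]];
      const double* Pm = P.memptr();
      for (arma::uword i = 0; i < m; ++i) {
        const double prec = Pm[i + m * i];
        double dot = 0.0;
        const double* Pi = Pm + i; // row i, column-major stride m
        for (arma::uword j = 0; j < m; ++j)
          dot += Pi[m * j] * (yb[j] - mu[j]);
        dot -= prec * (yb[i] - mu[i]);
        double cmean = mu[i] - dot / prec;
        double csd = std::sqrt(1.0 / prec);
        int cat = ycat[idxs[b][i]];
        yb[i] = rtruncnorm1(cmean, csd, cut[cat], cut[cat + 1]);
      }
      for (arma::uword i = 0; i < m; ++i) ystar[idxs[b][i]] = yb[i];
      // accumulate the GLS pieces for the collapsed fixed-effect update
      arma::mat& PX = PXw[b];
      PX = P * Xb[b];
      XtViX += Xb[b].t() * PX;
      XtViy += PX.t() * yb;
    }

    // 2. fixed effects from the collapsed GLS conditional
    {
      arma::mat LT = arma::chol(XtViX, "upper");
      arma::vec mean_b = arma::solve(arma::trimatu(LT),
                         arma::solve(arma::trimatl(LT.t()), XtViy));
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
      bcoef = mean_b + arma::solve(arma::trimatu(LT), z);
    }

    // 3. random effects redrawn exactly, per block
    arma::vec uQu(ncomp, arma::fill::zeros);
    for (int b = 0; b < nb; ++b) {
      const arma::uword M = Zs[b].n_cols;
      arma::mat& P = Pu[b];
      P = ZtZ[b];
      P /= sigma2e;
      int off = 0;
      for (int c = 0; c < ncomp; ++c) {
        int qc = qss[b][c];
        if (qc > 0)
          P.submat(off, off, off + qc - 1, off + qc - 1) +=
            Qs[b][c] / sigma2[c];
        off += qc;
      }
      arma::vec& rhs = rhsw[b];
      rhs = Zs[b].t() * (ybw[b] - Xb[b] * bcoef);
      rhs /= sigma2e;
      arma::mat& LT = LTw[b];
      arma::chol(LT, P, "upper");
      arma::vec& z = zw[b];
      for (arma::uword j = 0; j < M; ++j) z[j] = R::norm_rand();
      arma::vec& u = uw[b];
      u = arma::solve(arma::trimatl(LT.t()), rhs);
      u = arma::solve(arma::trimatu(LT), u + z);
      us[b] = u;
      off = 0;
      for (int c = 0; c < ncomp; ++c) {
        int qc = qss[b][c];
        if (qc > 0) {
          arma::vec uc = us[b].subvec(off, off + qc - 1);
          uQu[c] += arma::as_scalar(uc.t() * Qs[b][c] * uc);
        }
        off += qc;
      }
    }

    // 4. variance components: scaled inverse chi-squared full conditionals
    for (int c = 0; c < ncomp; ++c) {
      double df = comp_q_total[c] + prior_df;
      double ss = uQu[c] + prior_df * prior_scale;
      sigma2[c] = ss / R::rchisq(df);
    }
    if (free_resid) {
      // the residual takes a proper (df >= 1) prior: with per-individual
      // random effects an ordinal likelihood stays positive as
      // sigma2e -> 0, and a near-flat prior makes that corner an
      // absorbing spike
      arma::vec e = ystar - X * bcoef;
      for (int b = 0; b < nb; ++b)
        e.elem(idxs[b]) -= Zs[b] * us[b];
      double ss = arma::dot(e, e) + prior_df_resid * prior_scale_resid;
      sigma2e = ss / R::rchisq(n + prior_df_resid);
    }

    // record
    if (it >= burnin && (it - burnin) % thin == 0 && isave < nsave) {
      eta = X * bcoef; // shared-effects linear predictor (DIC focus)
      for (int b = 0; b < nb; ++b)
        eta.elem(idxs[b]) += Zsh[b] * us[b].elem(shared_cols[b]);
      arma::vec v_i(n);
      v_i.fill(sigma2e);
      for (int c = 0; c < ncomp; ++c)
        v_i += sigma2[c] * sing.col(c);
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        int c = ycat[i];
        double sde = std::sqrt(v_i[i]);
        double hi = (cut[c + 1] == R_PosInf) ? 1.0 :
          R::pnorm((cut[c + 1] - eta[i]) / sde, 0.0, 1.0, 1, 0);
        double lo = (cut[c] == R_NegInf) ? 0.0 :
          R::pnorm((cut[c] - eta[i]) / sde, 0.0, 1.0, 1, 0);
        dev += -2.0 * std::log(std::max(hi - lo, 1e-300));
      }
      sigma_trace.row(isave) = sigma2.t();
      resid_trace[isave] = sigma2e;
      b_trace.row(isave) = bcoef.t();
      dev_trace[isave] = dev;
      mean_eta += eta;
      mean_vi += v_i;
      ++isave;
    }
  }

  mean_eta /= std::max(1, isave);
  mean_vi /= std::max(1, isave);
  double dev_at_means = 0.0;
  for (int i = 0; i < n; ++i) {
    int c = ycat[i];
    double sde = std::sqrt(mean_vi[i]);
    double hi = (cut[c + 1] == R_PosInf) ? 1.0 :
      R::pnorm((cut[c + 1] - mean_eta[i]) / sde, 0.0, 1.0, 1, 0);
    double lo = (cut[c] == R_NegInf) ? 0.0 :
      R::pnorm((cut[c] - mean_eta[i]) / sde, 0.0, 1.0, 1, 0);
    dev_at_means += -2.0 * std::log(std::max(hi - lo, 1e-300));
  }

  return List::create(_["sigma_trace"] = sigma_trace,
                      _["resid_trace"] = resid_trace,
                      _["b_trace"] = b_trace,
                      _["deviance_trace"] = dev_trace,
                      _["deviance_at_means"] = dev_at_means,
                      _["n_saved"] = isave);
}
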