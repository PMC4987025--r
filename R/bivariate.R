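#' Bivariate variance-component model for two traits
#'
#' Fits, by AI-REML, a two-trait mixed model in which every random
#' component (additive-genetic, shared spouse/partner environment, and
#' residual) carries an unstructured 2x2 covariance block. The
#' cross-trait correlation of each component is the off-diagonal divided
#' by the geometric mean of the trait variances; standard errors come
#' from the delta method on the inverse average-information matrix.
#' Individuals missing one trait contribute to the other trait only
#' (pairwise-complete likelihood).
#'
#' @param phenotypes data.frame with `id`, both traits, covariates.
#' @param traits length-2 character vector of trait column names; both
#'   are analysed on their numeric working scale (a 0/1 indicator for a
#'   binary disease trait).
#' @param structures named list of `relationship_structure`s; `additive`
#'   is required, further entries (e.g. `spouse`) are the shared
#'   environments retained from the univariate model. A residual block is
#'   always added.
#' @param fixed_effects as in [mixed_model_spec()]; applied per trait.
#' @param constraint `NULL` for the full model, `"rg"` to pin the
#'   additive cross-covariance at zero, or `"r_env"` to pin the
#'   cross-covariance of the (first) shared-environment component; used
#'   to build the nested null models of the correlation tests.
#' @param init optional named starting values for the covariance
#'   parameters (`<component>.v1` / `.c12` / `.v2`); parameters absent
#'   from `init` start at 0 (off-diagonals) or an equal share of the
#'   trait variance. Warm-starting the full model from its constrained
#'   null keeps the likelihood-ratio comparison nested even in hard
#'   corners of the parameter space.
#' @return A `bivar_fit`: per-component 2x2 blocks, component
#'   correlations with SEs, the fixed-effect-adjusted phenotypic
#'   correlation with SE, the raw Pearson correlation, the restricted
#'   log-likelihood and bookkeeping counts.
#' @export
fit_bivariate_reml <- function(phenotypes, traits, structures,
                               fixed_effects = c("sex", "age", "age2"),
                               constraint = NULL, init = NULL) {
  stopifnot(length(traits) == 2)
  if (!"additive" %in% names(structures))
    stop("the bivariate model requires an 'additive' structure")
  dat <- phenotypes
  covars <- if (inherits(fixed_effects, "formula")) all.vars(fixed_effects)
  else setdiff(ifelse(fixed_effects == "age2", "age", fixed_effects), "")
  covars <- intersect(unique(covars), names(dat))

  obs <- lapply(traits, function(tr)
    which(stats::complete.cases(dat[, c(tr, covars), drop = FALSE])))
  if (any(lengths(obs) == 0)) stop("a trait has no complete observations")
  ids1 <- as.character(dat$id[obs[[1]]])
  ids2 <- as.character(dat$id[obs[[2]]])
  y1 <- as.numeric(dat[[traits[1]]][obs[[1]]])
  y2 <- as.numeric(dat[[traits[2]]][obs[[2]]])
  if (stats::var(y1) == 0 || stats::var(y2) == 0)
    stop("a trait has zero variance")
  n1 <- length(ids1); n2 <- length(ids2)
  y <- c(y1, y2)
  X1 <- fixed_design(fixed_effects, dat[obs[[1]], , drop = FALSE])
  X2 <- fixed_design(fixed_effects, dat[obs[[2]], , drop = FALSE])
  X <- as.matrix(Matrix::bdiag(X1, X2))

  comp_names <- c(names(structures), "residual")
  Ksubs <- c(lapply(structures, function(S) {
    K11 <- subset_structure(S, ids1)
    K22 <- subset_structure(S, ids2)
    K12 <- methods::as(S$matrix[ids1, ids2, drop = FALSE], "CsparseMatrix")
    list(K11 = K11, K22 = K22, K12 = K12)
  }), list(residual = {
    common <- intersect(ids1, ids2)
    R12 <- Matrix::sparseMatrix(i = match(common, ids1),
                                j = match(common, ids2), x = 1,
                                dims = c(n1, n2))
    list(K11 = methods::as(Matrix::Diagonal(n1), "CsparseMatrix"),
         K22 = methods::as(Matrix::Diagonal(n2), "CsparseMatrix"),
         K12 = methods::as(R12, "CsparseMatrix"))
  }))

  Z11 <- Matrix::Matrix(0, n1, n1, sparse = TRUE)
  Z22 <- Matrix::Matrix(0, n2, n2, sparse = TRUE)
  expand11 <- function(K) methods::as(Matrix::bdiag(K, Z22), "CsparseMatrix")
  expand22 <- function(K) methods::as(Matrix::bdiag(Z11, K), "CsparseMatrix")
  expand12 <- function(K12) {
    M <- rbind(cbind(Z11, K12), cbind(Matrix::t(K12), Z22))
    methods::as(M, "CsparseMatrix")
  }

  env_comp <- setdiff(names(structures), "additive")
  drop12 <- character(0)
  if (!is.null(constraint)) {
    drop12 <- switch(constraint,
      rg = "additive",
      r_env = {
        if (!length(env_comp))
          stop("no shared-environment component to constrain")
        env_comp[1]
      },
      stop("unknown constraint '", constraint,
           "' (expected \"rg\" or \"r_env\")"))
  }

  Glist <- list(); nonneg <- logical(0); pnames <- character(0)
  psd_groups <- list(); par_comp <- character(0); par_kind <- character(0)
  for (k in comp_names) {
    Ks <- Ksubs[[k]]
    i0 <- length(Glist)
    Glist[[length(Glist) + 1]] <- expand11(Ks$K11)
    pnames <- c(pnames, paste0(k, ".v1")); nonneg <- c(nonneg, TRUE)
    par_comp <- c(par_comp, k); par_kind <- c(par_kind, "v1")
    has12 <- !(k %in% drop12)
    if (has12) {
      Glist[[length(Glist) + 1]] <- expand12(Ks$K12)
      pnames <- c(pnames, paste0(k, ".c12")); nonneg <- c(nonneg, FALSE)
      par_comp <- c(par_comp, k); par_kind <- c(par_kind, "c12")
    }
    Glist[[length(Glist) + 1]] <- expand22(Ks$K22)
    pnames <- c(pnames, paste0(k, ".v2")); nonneg <- c(nonneg, TRUE)
    par_comp <- c(par_comp, k); par_kind <- c(par_kind, "v2")
    if (has12)
      psd_groups[[length(psd_groups) + 1]] <- c(i0 + 1, i0 + 2, i0 + 3)
  }
  names(Glist) <- pnames

  ncomp <- length(comp_names)
  init0 <- numeric(length(pnames))
  init0[par_kind == "v1"] <- stats::var(y1) / ncomp
  init0[par_kind == "v2"] <- stats::var(y2) / ncomp
  if (!is.null(init)) {
    hit <- match(pnames, names(init))
    init0[!is.na(hit)] <- init[hit[!is.na(hit)]]
  }
  eng <- reml_engine(y, X, Glist, nonneg = nonneg,
                     psd_groups = psd_groups, init = init0)
  if (!eng$converged)
    warning("bivariate REML did not converge")

  th <- stats::setNames(eng$theta, pnames)
  C <- eng$theta_cov
  blocks <- list(); cors <- data.frame()
  for (k in comp_names) {
    sel <- which(par_comp == k)
    v1 <- th[par_comp == k & par_kind == "v1"]
    v2 <- th[par_comp == k & par_kind == "v2"]
    c12 <- if (any(par_comp == k & par_kind == "c12"))
      th[par_comp == k & par_kind == "c12"] else 0
    blocks[[k]] <- matrix(c(v1, c12, c12, v2), 2, 2,
                          dimnames = list(traits, traits))
    r <- c12 / sqrt(v1 * v2)
    se <- NA_real_
    if (any(par_kind[sel] == "c12") && !anyNA(C)) {
      g <- c(-r / (2 * v1), 1 / sqrt(v1 * v2), -r / (2 * v2))
      se <- sqrt(max(drop(t(g) %*% C[sel, sel] %*% g), 0))
    }
    cors <- rbind(cors, data.frame(component = k,
                                   correlation = unname(r),
                                   se = unname(se),
                                   constrained = k %in% drop12))
  }

  v1t <- sum(th[par_kind == "v1"])
  v2t <- sum(th[par_kind == "v2"])
  ct <- sum(th[par_kind == "c12"])
  rp <- ct / sqrt(v1t * v2t)
  rp_se <- NA_real_
  if (!anyNA(C)) {
    g <- numeric(length(th))
    g[par_kind == "v1"] <- -rp / (2 * v1t)
    g[par_kind == "v2"] <- -rp / (2 * v2t)
    g[par_kind == "c12"] <- 1 / sqrt(v1t * v2t)
    rp_se <- sqrt(max(drop(t(g) %*% C %*% g), 0))
  }

  common <- intersect(ids1, ids2)
  pearson <- stats::cor(as.numeric(dat[[traits[1]]][match(common, dat$id)]),
                        as.numeric(dat[[traits[2]]][match(common, dat$id)]))
  n_pairs <- NA_integer_
  if (length(env_comp)) {
    gr <- attr(structures[[env_comp[1]]], "groups")
    if (!is.null(gr))
      n_pairs <- sum(vapply(gr, function(g)
        sum(g %in% common) >= 2, logical(1)))
  }

  structure(list(traits = traits, blocks = blocks, correlations = cors,
                 r_phenotypic = rp, r_phenotypic_se = rp_se,
                 pearson = pearson,
                 estimates = th, theta_cov = C,
                 log_likelihood = eng$logL, converged = eng$converged,
                 constraint = constraint, n_trait1 = n1, n_trait2 = n2,
                 n_both = length(common), n_pairs_informative = n_pairs),
            class = "bivar_fit")
}

#' @exportS3Method base::print
print.bivar_fit <- function(x, ...) {
  cat("<bivar_fit> traits ", paste(x$traits, collapse = " / "),
      if (!is.null(x$constraint)) paste0(" [", x$constraint, " = 0]"),
      "\n", sep = "")
  print(x$correlations, digits = 3)
  cat("adjusted phenotypic r = ", format(x$r_phenotypic, digits = 3),
      " (SE ", format(x$r_phenotypic_se, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Null model with a cross-trait covariance pinned at zero
#'
#' Refits the bivariate model with the named component's off-diagonal
#' fixed at 0 (diagonals free), giving the one-degree-of-freedom nested
#' null for the correlation tests.
#'
#' @inheritParams fit_bivariate_reml
#' @param constraint `"rg"` or `"r_env"`.
#' @export
constrained_fit <- function(phenotypes, traits, structures,
                            fixed_effects = c("sex", "age", "age2"),
                            constraint = c("rg", "r_env")) {
  constraint <- match.arg(constraint)
  fit_bivariate_reml(phenotypes, traits, structures, fixed_effects,
                     constraint = constraint)
}

#' Likelihood-ratio significance of a component correlation
#'
#' Compares the full bivariate fit with a constrained null by a
#' chi-squared test with one degree of freedom.
#'
#' @param full,null `bivar_fit`s on the same data.
#' @export
correlation_significance <- function(full, null) {
  likelihood_ratio_test(full, null, df = 1)
}

#' Fixed-effect-adjusted phenotypic correlation and its z-test
#'
#' The phenotypic correlation is the total (summed-component) cross-trait
#' covariance over the geometric mean of the total trait variances, from
#' a bivariate mixed model that adjusts for the fixed effects and for
#' relatedness. Its significance is the ratio of the estimate to its
#' standard error referred to a standard normal, two-tailed.
#'
#' @param x either a fitted `bivar_fit`, or a phenotype data.frame (then
#'   `traits` and `structures` are required and an additive + residual
#'   model is fitted).
#' @inheritParams fit_bivariate_reml
#' @return list with `estimate`, `se`, `z`, `p_value`, and the raw
#'   `pearson` correlation for comparison.
#' @export
adjusted_phenotypic_correlation <- function(x, traits = NULL,
                                            structures = NULL,
                                            fixed_effects = c("sex", "age",
                                                              "age2")) {
  fit <- if (inherits(x, "bivar_fit")) x
  else fit_bivariate_reml(x, traits, structures["additive"], fixed_effects)
  est <- fit$r_phenotypic; se <- fit$r_phenotypic_se
  if (is.na(se) || se == 0)
    stop("degenerate fit: phenotypic-correlation SE is zero or undefined")
  z <- est / se
  list(estimate = est, se = se, z = z,
       p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       pearson = fit$pearson)
}
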