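#' Specify a univariate mixed model for variance-component estimation
#'
#' Describes the response (and its measurement scale), the fixed effects
#' and the covariance-structured random components of an animal-model
#' style mixed model. Defaults follow the common epidemiological
#' adjustment set: sex, age and age squared.
#'
#' @param response name of the phenotype column.
#' @param scale `"gaussian"`, `"ordinal"` or `"binary"`. Ordinal and
#'   binary responses are modelled on the liability scale by the Gibbs
#'   backend; the REML backend fits them as numeric working scores.
#' @param fixed_effects character vector of covariate names; `"age2"` is
#'   understood as age squared. May also be a one-sided formula.
#' @param random_components character vector naming the relationship
#'   structures to include (a residual term is always added).
#' @param priors list with `df` and `scale` of the scaled
#'   inverse-chi-squared prior on each variance component (Gibbs
#'   backend). The default (scale 1, df 0.002) is the conventional
#'   weakly-informative variance prior of Bayesian animal models; it is
#'   nearly flat on the log scale and keeps mass near zero so null
#'   components can be recovered.
#' @param mcmc_control list with `iterations`, `burn_in`, `thin`,
#'   `chains`; see [mcmc_profile()].
#' @return A `mixed_model_spec` object.
#' @export
mixed_model_spec <- function(response,
                             scale = c("gaussian", "ordinal", "binary"),
                             fixed_effects = c("sex", "age", "age2"),
                             random_components = "additive",
                             priors = list(df = 0.002, scale = 1),
                             mcmc_control = mcmc_profile("paper")) {
  scale <- match.arg(scale)
  stopifnot(length(random_components) >= 1,
            mcmc_control$iterations > 0, mcmc_control$burn_in >= 0,
            mcmc_control$thin > 0)
  structure(list(response = response, scale = scale,
                 fixed_effects = fixed_effects,
                 random_components = random_components,
                 priors = priors, mcmc_control = mcmc_control),
            class = "mixed_model_spec")
}

#' MCMC run-length profiles
#'
#' `"paper"` is the long production profile (85,000 iterations, 15,000
#' burn-in, thinning interval 50, three chains); `"fast"` is a short
#' profile for desk-scale runs and simulation studies (5,000 / 1,000 / 5).
#'
#' @param profile `"paper"` or `"fast"`.
#' @param chains number of chains.
#' @export
mcmc_profile <- function(profile = c("paper", "fast"), chains = 3) {
  profile <- match.arg(profile)
  ctl <- switch(profile,
                paper = list(iterations = 85000, burn_in = 15000, thin = 50),
                fast = list(iterations = 5000, burn_in = 1000, thin = 5))
  ctl$chains <- chains
  ctl
}

# build the fixed-effects design matrix from a covariate specification
fixed_design <- function(fixed_effects, data) {
  if (inherits(fixed_effects, "formula")) {
    fml <- fixed_effects
  } else {
    terms <- vapply(fixed_effects, function(v) {
      if (v == "age2") "I(age^2)" else v
    }, character(1))
    fml <- stats::reformulate(if (length(terms)) terms else "1")
  }
  df <- data
  if ("sex" %in% names(df)) df$sex <- factor(df$sex)
  X <- stats::model.matrix(fml, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular fixed-effects design (rank ", qrX$rank, " < ",
         ncol(X), " columns)")
  X
}

# align relationship structures to the ids of the analysis rows
subset_structure <- function(S, ids) {
  miss <- setdiff(ids, S$ids)
  if (length(miss))
    stop("structure '", S$kind, "' is missing ids: ",
         paste(utils::head(miss, 5), collapse = ", "))
  methods::as(S$matrix[ids, ids], "CsparseMatrix")
}

#' Fit a univariate variance-component model by AI-REML
#'
#' Restricted maximum likelihood with average-information updates and a
#' fixed-point fallback whenever an update leaves the parameter space.
#' Variance components are constrained non-negative; standard errors come
#' from the inverse average-information matrix and proportion intervals
#' from the delta method. Convergence is declared when the change in the
#' restricted log-likelihood falls below `tol`.
#'
#' @param spec a [mixed_model_spec()] (ordinal/binary responses are fitted
#'   as numeric working scores under this backend).
#' @param phenotypes data.frame with columns `id`, the response, and the
#'   fixed-effect covariates.
#' @param structures named list of `relationship_structure` objects; must
#'   cover `spec$random_components`.
#' @param tol,max_iter convergence tolerance and iteration cap.
#' @return A `vc_fit` with per-component variance estimates and standard
#'   errors, variance proportions with 95% intervals, fixed-effect
#'   estimates, the restricted log-likelihood, and a convergence flag.
#' @export
fit_reml <- function(spec, phenotypes, structures, tol = 1e-6,
                     max_iter = 100) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  comp <- spec$random_components
  if (!all(comp %in% names(structures)))
    stop("structures missing for component(s): ",
         paste(setdiff(comp, names(structures)), collapse = ", "))
  dat <- phenotypes
  covars <- if (inherits(spec$fixed_effects, "formula"))
    all.vars(spec$fixed_effects)
  else setdiff(ifelse(spec$fixed_effects == "age2", "age",
                      spec$fixed_effects), "")
  covars <- intersect(unique(covars), names(dat))
  keep_rows <- which(stats::complete.cases(
    dat[, c(spec$response, covars), drop = FALSE]))
  ids <- as.character(dat$id[keep_rows])
  y <- as.numeric(dat[[spec$response]][keep_rows])
  X <- fixed_design(spec$fixed_effects, dat[keep_rows, , drop = FALSE])

  Glist <- lapply(structures[comp], subset_structure, ids = ids)
  Glist$residual <- methods::as(Matrix::Diagonal(length(ids)),
                                "CsparseMatrix")
  eng <- reml_engine(y, X, Glist, nonneg = rep(TRUE, length(Glist)),
                     max_iter = max_iter, tol = tol)
  if (!eng$converged)
    warning("REML did not converge in ", max_iter, " iterations")
  est <- stats::setNames(eng$theta, names(Glist))
  se <- stats::setNames(eng$se, names(Glist))
  fe <- data.frame(term = colnames(X), estimate = eng$beta,
                   se = sqrt(pmax(diag(as.matrix(eng$beta_cov)), 0)))
  fit <- structure(list(backend = "reml", estimates = est, se = se,
                        theta_cov = eng$theta_cov,
                        fixed_effects = fe,
                        log_likelihood = eng$logL,
                        converged = eng$converged,
                        iterations = eng$iterations,
                        n_used = eng$n, spec = spec, ids = ids),
                   class = "vc_fit")
  fit$proportions <- variance_proportions(fit)
  fit
}

#' @exportS3Method base::print
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> backend=", x$backend, ", n=", x$n_used, "\n", sep = "")
  print(x$proportions, digits = 4)
  if (x$backend == "reml")
    cat("restricted logL:", format(x$log_likelihood), "\n")
  else
    cat("DIC:", format(x$dic), "\n")
  invisible(x)
}

#' Variance-component proportions of total variance
#'
#' Each component's share of the total phenotypic variance (all random
#' components plus residual). For REML fits the 95% intervals come from
#' the delta method on the inverse average-information matrix; for Gibbs
#' fits they are posterior quantiles of the per-draw ratios on the
#' liability scale (residual fixed at 1). A bare named numeric vector of
#' component variances is also accepted, returning the plain
#' normalization.
#'
#' @param fit a `vc_fit`, or a named numeric vector of variances.
#' @return data.frame with columns `component`, `variance`, `proportion`,
#'   `lower`, `upper`.
#' @export
variance_proportions <- function(fit) {
  if (is.numeric(fit)) {
    tot <- sum(fit)
    if (tot <= 0) stop("zero total variance: proportions undefined")
    return(data.frame(component = names(fit), variance = unname(fit),
                      proportion = unname(fit) / tot,
                      lower = NA_real_, upper = NA_real_))
  }
  stopifnot(inherits(fit, "vc_fit"))
  if (fit$backend == "gibbs") {
    sam <- fit$samples # draws x components (incl residual)
    tot <- rowSums(sam)
    props <- sweep(sam, 1, tot, "/")
    qs <- apply(props, 2, stats::quantile, probs = c(0.025, 0.975))
    return(data.frame(component = colnames(sam),
                      variance = unname(colMeans(sam)),
                      proportion = unname(colMeans(props)),
                      lower = unname(qs[1, ]), upper = unname(qs[2, ])))
  }
  th <- fit$estimates
  tot <- sum(th)
  if (tot <= 0) stop("zero total variance: proportions undefined")
  C <- fit$theta_cov
  np <- length(th)
  out <- data.frame(component = names(th), variance = unname(th),
                    proportion = unname(th) / tot,
                    lower = NA_real_, upper = NA_real_)
  if (!anyNA(C)) {
    for (k in seq_len(np)) {
      g <- -th[k] / tot^2 * rep(1, np)
      g[k] <- g[k] + 1 / tot
      v <- drop(t(g) %*% C %*% g)
      s <- sqrt(max(v, 0))
      out$lower[k] <- max(0, out$proportion[k] - 1.96 * s)
      out$upper[k] <- min(1, out$proportion[k] + 1.96 * s)
    }
  }
  out
}

#' Likelihood-ratio test between nested REML fits
#'
#' The statistic is twice the difference in restricted log-likelihood,
#' referred to an upper-tail chi-squared with `df` degrees of freedom.
#' When a variance component is tested on its boundary, the optional
#' boundary correction uses an equal mixture of chi-squared `df` and
#' `df - 1` (a point mass at zero when `df = 1`).
#'
#' @param fit_full,fit_null nested fits (objects with `log_likelihood`,
#'   or bare numeric log-likelihoods).
#' @param df degrees of freedom of the comparison.
#' @param boundary use the 50:50 mixture correction.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_null, df = 1,
                                  boundary = FALSE) {
  ll <- function(f) if (is.numeric(f)) f else f$log_likelihood
  l1 <- ll(fit_full); l0 <- ll(fit_null)
  if (l1 < l0 - 1e-6)
    stop("full model has lower log-likelihood than null: fits not nested ",
         "or not converged (difference ", format(l1 - l0), ")")
  stat <- max(0, 2 * (l1 - l0))
  p <- if (boundary) {
    p_hi <- stats::pchisq(stat, df, lower.tail = FALSE)
    p_lo <- if (df - 1 > 0) stats::pchisq(stat, df - 1, lower.tail = FALSE)
            else as.numeric(stat <= 0)
    0.5 * p_hi + 0.5 * p_lo
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p)
}
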