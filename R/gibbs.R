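#' Fit an ordinal or binary trait by a probit threshold-model Gibbs sampler
#'
#' Liability-scale Bayesian mixed model fitted by a partially collapsed
#' Gibbs sampler: latent liabilities and fixed effects are updated under
#' the per-family marginal covariance (random effects integrated out,
#' which removes the slow mixing of the centred sampler), random effects
#' are then redrawn exactly, and variance components come from their
#' scaled inverse-chi-squared full conditionals. Identification: binary
#' traits use the probit convention (threshold 0, residual variance 1);
#' ordinal traits fix all cutpoints at observed-frequency normal
#' quantiles and free the residual variance. Reported proportions are
#' liability-scale shares. DIC uses the marginal family-level deviance
#' (random effects integrated out by GHK estimation), the form suited to
#' comparing covariance structures. Several chains are run by default
#' and their agreement checked; mixing is flagged through per-component
#' effective sample sizes.
#'
#' @inheritParams fit_reml
#' @param cache optional environment shared across fits of nested models
#'   on the same data (as in stepwise selection): the per-family block
#'   preparation is computed once for the union of all structures and
#'   reused, which does not change any result.
#' @return A `vc_fit` with posterior means/modes, 95% credible intervals,
#'   liability-scale proportions, DIC, per-component effective sample
#'   sizes and the thinned posterior draws.
#' @export
fit_gibbs_ordinal <- function(spec, phenotypes, structures, cache = NULL) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  if (!spec$scale %in% c("ordinal", "binary"))
    stop("the Gibbs backend is for ordinal or binary responses; use ",
         "fit_reml() for gaussian-scale traits")
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
  keep <- which(stats::complete.cases(
    dat[, c(spec$response, covars), drop = FALSE]))
  ids <- as.character(dat$id[keep])
  yraw <- dat[[spec$response]][keep]
  lev <- sort(unique(as.numeric(yraw)))
  K <- length(lev)
  if (K < 2) stop("response has a single observed category")
  full_range <- seq(min(lev), max(lev))
  if (spec$scale == "ordinal" && !all(full_range %in% lev))
    stop("response category with zero observations: ",
         paste(setdiff(full_range, lev), collapse = ", "))
  ycat <- match(as.numeric(yraw), lev) - 1L
  X <- fixed_design(spec$fixed_effects, dat[keep, , drop = FALSE])

  if (!is.null(cache) && !is.null(cache$parts) &&
        identical(cache$ids, ids) &&
        all(comp %in% names(cache$parts))) {
    binfo <- assemble_gibbs_blocks(cache, comp)
  } else if (!is.null(cache)) {
    # prepare once over the union partition of ALL supplied structures;
    # a coarser partition stays block diagonal for every sub-model
    Kall <- lapply(structures, subset_structure, ids = ids)
    cache$ids <- ids
    cache$blocks_idx <- covariance_blocks(Kall, length(ids))
    cache$parts <- prepare_gibbs_parts(structures, Kall, ids,
                                       cache$blocks_idx)
    binfo <- assemble_gibbs_blocks(cache, comp)
  } else {
    Ksub <- lapply(structures[comp], subset_structure, ids = ids)
    blocks_idx <- covariance_blocks(Ksub, length(ids))
    env <- new.env()
    env$ids <- ids
    env$blocks_idx <- blocks_idx
    env$parts <- prepare_gibbs_parts(structures[comp], Ksub, ids,
                                     blocks_idx)
    binfo <- assemble_gibbs_blocks(env, comp)
  }

  ctl <- spec$mcmc_control
  chains <- max(1L, ctl$chains %||% 1L)
  ncomp <- length(comp)
  free_resid <- K > 2
  cut_fixed <- if (K == 2) c(-Inf, 0, Inf)
  else { # cutpoints at observed-frequency normal quantiles
    cum <- cumsum(tabulate(ycat + 1L, nbins = K)) / length(ycat)
    c(-Inf, stats::qnorm(cum[-K]), Inf)
  }
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    runs[[ch]] <- gibbs_ordinal_cpp(
      ycat = ycat, K = K, X = X, blocks = binfo$blocks,
      sing = binfo$sing, ncomp = ncomp,
      comp_q_total = binfo$comp_q_total,
      prior_df = spec$priors$df, prior_scale = spec$priors$scale,
      prior_df_resid = spec$priors$df_resid %||% 1,
      prior_scale_resid = spec$priors$scale_resid %||% 1,
      cut_fixed = cut_fixed, free_resid = free_resid,
      niter = ctl$iterations, burnin = ctl$burn_in, thin = ctl$thin,
      sigma_start = rep(stats::var(ycat) / (ncomp + 1) + 0.1, ncomp))
  }

  sig <- do.call(rbind, lapply(runs, `[[`, "sigma_trace"))
  colnames(sig) <- comp
  samples <- cbind(sig,
                   residual = unlist(lapply(runs, `[[`, "resid_trace")))
  btr <- do.call(rbind, lapply(runs, `[[`, "b_trace"))
  colnames(btr) <- colnames(X)

  # DIC deviance: marginal family-level likelihood (random effects and
  # residual integrated out by GHK), evaluated on a thinned subsample of
  # draws with a fixed uniform-deviate panel so competing models on the
  # same data share simulation noise
  pick <- unique(round(seq(1, nrow(samples), length.out =
                             min(64, nrow(samples)))))
  U <- with_preserved_seed(20240915L,
                           matrix(stats::runif(32 * length(ids)), 32))
  dev <- ghk_deviance_cpp(ycat, X, binfo$blocks, ncomp, cut_fixed,
                          btr[pick, , drop = FALSE],
                          sig[pick, , drop = FALSE],
                          samples[pick, "residual"], U)
  dev_at_means <- ghk_deviance_cpp(ycat, X, binfo$blocks, ncomp,
                                   cut_fixed,
                                   matrix(colMeans(btr), 1),
                                   matrix(colMeans(sig), 1),
                                   mean(samples[, "residual"]), U)[1]

  ess <- apply(sig, 2, effective_sample_size) # pooled, conservative
  if (any(ess < 100))
    warning("low effective sample size (< 100) for component(s): ",
            paste(comp[ess < 100], collapse = ", "),
            "; consider a longer chain")
  chain_disc <- NA_real_
  if (chains > 1) {
    cm <- sapply(runs, function(r) colMeans(r$sigma_trace))
    cm <- matrix(cm, nrow = ncomp)
    chain_disc <- max(apply(cm, 1, function(v) diff(range(v))))
  }

  est <- colMeans(samples)
  mode1 <- function(x) {
    if (stats::var(x) == 0) return(x[1])
    d <- stats::density(x)
    d$x[which.max(d$y)]
  }
  post_mode <- apply(samples, 2, mode1)
  ci <- apply(sig, 2, stats::quantile, probs = c(0.025, 0.975))
  fe <- data.frame(term = colnames(X), estimate = colMeans(btr),
                   se = apply(btr, 2, stats::sd))

  fit <- structure(list(backend = "gibbs", estimates = est,
                        posterior_mode = post_mode,
                        se = apply(samples, 2, stats::sd),
                        credible = ci, fixed_effects = fe,
                        fixed_samples = btr,
                        samples = samples,
                        deviance_trace = dev,
                        deviance_at_means = dev_at_means,
                        ess = ess, chain_discrepancy = chain_disc,
                        n_used = length(ids), n_chains = chains,
                        spec = spec, ids = ids),
                   class = "vc_fit")
  fit$dic <- dic(fit)
  fit$proportions <- variance_proportions(fit)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a fixed seed without disturbing the caller's
# RNG stream
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- force(expr)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

# Per-structure incidence/precision pieces for the sampler, computed per
# block of the supplied partition: the additive component uses
# per-individual effects with the inverse relationship block as prior
# precision; group-share components use group-level effects (identity
# prior precision), singletons included, which reproduces the 0/1 block
# covariance exactly.
prepare_gibbs_parts <- function(structs, Ksub, ids, blocks_idx) {
  nb <- length(blocks_idx)
  group_maps <- mapply(function(S, Kc) {
    if (S$kind == "additive") return(NULL)
    groups <- attr(S, "groups")
    if (is.null(groups)) { # derive the partition from the block pattern
      bl <- covariance_blocks(list(Kc), length(ids))
      groups <- lapply(bl, function(ix) ids[ix])
    }
    gm <- integer(length(ids)); names(gm) <- ids
    gi <- 0L
    for (g in groups) {
      g2 <- intersect(g, ids)
      if (length(g2)) { gi <- gi + 1L; gm[g2] <- gi }
    }
    for (i in which(gm == 0L)) { gi <- gi + 1L; gm[i] <- gi }
    gm
  }, structs, Ksub, SIMPLIFY = FALSE)
  parts <- vector("list", length(structs))
  names(parts) <- names(structs)
  for (c in seq_along(structs)) {
    S <- structs[[c]]
    per_block <- vector("list", nb)
    sing_c <- numeric(length(ids))
    for (b in seq_len(nb)) {
      idx <- blocks_idx[[b]]
      m <- length(idx)
      Kb <- as.matrix(Ksub[[c]][idx, idx, drop = FALSE])
      if (S$kind == "additive") {
        per_block[[b]] <- list(Z = diag(1, m), Q = solve(Kb), K = Kb,
                               q = m, shared = rep(1L, m))
      } else {
        gm <- group_maps[[c]][idx]
        glev <- sort(unique(gm))
        gsize <- table(group_maps[[c]])[as.character(glev)]
        q <- length(glev)
        Z <- matrix(0, m, q)
        Z[cbind(seq_len(m), match(gm, glev))] <- 1
        per_block[[b]] <- list(Z = Z, Q = diag(1, q), K = Kb, q = q,
                               shared = as.integer(gsize >= 2))
        sing_c[idx[gsize[match(gm, glev)] < 2]] <- 1
      }
    }
    parts[[c]] <- list(blocks = per_block, sing = sing_c)
  }
  parts
}

# assemble the sampler's block list for a component subset from the
# prepared per-structure pieces
assemble_gibbs_blocks <- function(env, comp) {
  nb <- length(env$blocks_idx)
  ncomp <- length(comp)
  blocks <- vector("list", nb)
  comp_q_total <- numeric(ncomp)
  sing <- do.call(cbind, lapply(env$parts[comp], `[[`, "sing"))
  for (b in seq_len(nb)) {
    pz <- lapply(env$parts[comp], function(p) p$blocks[[b]])
    qs <- vapply(pz, `[[`, numeric(1), "q")
    blocks[[b]] <- list(idx = as.integer(env$blocks_idx[[b]]),
                        Z = do.call(cbind, lapply(pz, `[[`, "Z")),
                        Q = lapply(pz, `[[`, "Q"),
                        K = lapply(pz, `[[`, "K"),
                        qs = qs,
                        shared = unlist(lapply(pz, `[[`, "shared")))
    comp_q_total <- comp_q_total + qs
  }
  list(blocks = blocks, comp_q_total = comp_q_total, sing = sing)
}

#' Deviance information criterion of a Gibbs fit
#'
#' `DIC = mean deviance + p_D`, where the effective parameter count
#' `p_D` is the mean deviance minus the deviance at the posterior means.
#' Larger values indicate poorer-fitting models.
#'
#' @param fit a `vc_fit` from [fit_gibbs_ordinal()], or any list with a
#'   `deviance_trace` and `deviance_at_means`.
#' @return scalar DIC.
#' @export
dic <- function(fit) {
  if (is.null(fit$deviance_trace))
    stop("no stored deviance trace: DIC requires an MCMC fit")
  dbar <- mean(fit$deviance_trace)
  pd <- dbar - fit$deviance_at_means
  dbar + pd
}

#' Effective sample size of an MCMC trace
#'
#' `n / (1 + 2 * sum(rho_k))`, summing autocorrelations until the first
#' negative lag (initial positive sequence estimator).
#'
#' @param x numeric chain.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(1000, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (is.na(r) || r < 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}
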