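# Internal AI-REML engine for variance models linear in their parameters:
#   V(theta) = sum_k theta_k G_k
# with V block diagonal over the connected components of the combined
# sparsity pattern (independent families). The per-iteration likelihood,
# score and average-information evaluations run in compiled code over the
# dense per-block pieces; this file handles blocking, packing, the Newton
# loop with step-halving, non-negativity clamps and PSD repair.

covariance_blocks <- function(Glist, n) {
  ii <- integer(0); jj <- integer(0)
  for (G in Glist) {
    Gg <- methods::as(methods::as(G, "generalMatrix"), "TsparseMatrix")
    keep <- Gg@i < Gg@j
    ii <- c(ii, Gg@i[keep] + 1L)
    jj <- c(jj, Gg@j[keep] + 1L)
  }
  membership <- graph_components(n, ii, jj)
  blocks <- split(seq_len(n), membership)
  names(blocks) <- NULL
  blocks
}

# connected components by label propagation on a vectorized edge list;
# components are numbered by their smallest member so the order is
# deterministic
graph_components <- function(n, ii, jj) {
  lab <- seq_len(n)
  if (length(ii)) {
    repeat {
      li <- pmin(lab[ii], lab[jj])
      changed <- FALSE
      m1 <- tapply(li, ii, min)
      idx1 <- as.integer(names(m1))
      upd <- m1 < lab[idx1]
      if (any(upd)) { lab[idx1[upd]] <- m1[upd]; changed <- TRUE }
      m2 <- tapply(li, jj, min)
      idx2 <- as.integer(names(m2))
      upd <- m2 < lab[idx2]
      if (any(upd)) { lab[idx2[upd]] <- m2[upd]; changed <- TRUE }
      # path compression
      lab2 <- lab[lab]
      if (any(lab2 != lab)) { lab <- lab2; changed <- TRUE }
      if (!changed) break
    }
  }
  match(lab, sort(unique(lab)))
}

pack_blocks <- function(G, blocks) {
  n <- nrow(G)
  block_of <- integer(n); pos_in <- integer(n)
  for (b in seq_along(blocks)) {
    block_of[blocks[[b]]] <- b
    pos_in[blocks[[b]]] <- seq_along(blocks[[b]])
  }
  Gg <- methods::as(methods::as(G, "generalMatrix"), "TsparseMatrix")
  i <- Gg@i + 1L; j <- Gg@j + 1L; x <- Gg@x
  eb <- block_of[i]
  byb <- split(seq_along(i), factor(eb, levels = seq_along(blocks)))
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    m <- length(blocks[[b]])
    M <- matrix(0, m, m)
    e <- byb[[b]]
    if (length(e))
      M[cbind(pos_in[i[e]], pos_in[j[e]])] <- x[e]
    out[[b]] <- M
  }
  out
}

#' @keywords internal
reml_engine <- function(y, X, Glist, nonneg = rep(TRUE, length(Glist)),
                        psd_groups = NULL, init = NULL,
                        max_iter = 100, tol = 1e-6) {
  n <- length(y)
  np <- length(Glist)
  blocks <- covariance_blocks(Glist, n)
  Gpack <- lapply(Glist, pack_blocks, blocks = blocks)
  vy <- stats::var(y)
  lb <- 1e-8 * vy

  theta <- if (is.null(init)) {
    th <- numeric(np)
    th[nonneg] <- vy / sum(nonneg)
    th
  } else init
  theta <- repair_theta(theta, nonneg, lb, psd_groups)

  ev <- reml_eval(theta, blocks, y, X, Gpack)
  if (!isTRUE(ev$ok)) stop("variance model not positive definite at the starting values")
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    AI <- ev$AI
    score <- drop(ev$score)
    delta <- tryCatch(solve(AI + diag(1e-6 * max(diag(AI)), np), score),
                      error = function(e) NULL)
    if (!is.null(delta)) {
      # trust region: a near-singular average-information matrix (e.g. at
      # a perfectly correlated boundary) must not launch the parameters
      # out of the feasible region
      cap <- max(abs(delta) / (10 * (abs(theta) + 0.1 * vy)))
      if (cap > 1) delta <- delta / cap
    }
    accepted <- FALSE
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:20) {
        cand <- repair_theta(theta + step * delta, nonneg, lb, psd_groups)
        ev2 <- reml_eval(cand, blocks, y, X, Gpack)
        if (isTRUE(ev2$ok) && ev2$logL >= ev$logL - 1e-10) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      # fixed-point (EM-flavoured) fallback: multiplicative, stays in the
      # parameter space for variance parameters
      cand <- theta
      for (k in which(nonneg)) {
        tk <- drop(ev$trPG)[k]
        if (tk > 0) cand[k] <- theta[k] * drop(ev$q)[k] / tk
      }
      cand <- repair_theta(cand, nonneg, lb, psd_groups)
      ev2 <- reml_eval(cand, blocks, y, X, Gpack)
      improved <- isTRUE(ev2$ok) && ev2$logL >= ev$logL - 1e-10
      if (!improved) {
        # damped gradient ascent as a last resort (moves covariance
        # parameters the fixed point cannot touch)
        gs <- score / max(abs(score), 1e-12) * 0.05 * vy
        for (h in 1:15) {
          cand <- repair_theta(theta + gs, nonneg, lb, psd_groups)
          ev2 <- reml_eval(cand, blocks, y, X, Gpack)
          if (isTRUE(ev2$ok) && ev2$logL >= ev$logL - 1e-10) {
            improved <- TRUE
            break
          }
          gs <- gs / 2
        }
      }
      if (!improved) break
    }
    dlog <- abs(ev2$logL - ev$logL)
    theta <- cand
    ev <- ev2
    if (dlog < tol) { converged <- TRUE; break }
  }

  theta_cov <- tryCatch(solve(ev$AI), error = function(e)
    matrix(NA_real_, np, np))
  list(theta = theta, theta_cov = theta_cov,
       se = sqrt(pmax(diag(theta_cov), 0)),
       logL = ev$logL, beta = drop(ev$beta), beta_cov = ev$beta_cov,
       converged = converged, iterations = iter, n = n,
       score = drop(ev$score))
}

repair_theta <- function(theta, nonneg, lb, psd_groups) {
  theta[nonneg] <- pmax(theta[nonneg], lb)
  if (!is.null(psd_groups)) {
    for (g in psd_groups) { # g = c(index v11, index v12, index v22)
      bound <- (1 - 1e-5) * sqrt(theta[g[1]] * theta[g[3]])
      if (abs(theta[g[2]]) > bound)
        theta[g[2]] <- sign(theta[g[2]]) * bound
    }
  }
  theta
}
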