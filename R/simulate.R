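#' Design of a simulated family cohort
#'
#' @param n_families number of independent families.
#' @param generations pedigree depth (2 = founder couple + children).
#' @param offspring_dist sibship-size distribution: `list(type =
#'   "constant", k = 2)` or `list(type = "poisson", lambda = 2.2)`.
#' @param couple_rate probability that a non-founder of the middle
#'   generations partners (with an immigrant founder) and reproduces.
#' @param household_rule `"couple_plus_minors"` (each couple and its
#'   never-partnered offspring form one household) or `"none"`.
#' @export
cohort_design <- function(n_families = 1000, generations = 3,
                          offspring_dist = list(type = "poisson",
                                                lambda = 2.2),
                          couple_rate = 0.6,
                          household_rule = c("couple_plus_minors", "none")) {
  stopifnot(n_families >= 1, generations >= 2)
  structure(list(n_families = n_families, generations = generations,
                 offspring_dist = offspring_dist,
                 couple_rate = couple_rate,
                 household_rule = match.arg(household_rule)),
            class = "cohort_design")
}

#' Liability-scale simulation truth for the two-trait family model
#'
#' Defines the generative variance decomposition shared by both traits
#' (an ordinal chronic-pain grade and a binary depression status), their
#' cross-trait correlations, the grade thresholds and disease prevalence,
#' and the fixed effects of sex, age and age squared.
#'
#' @param h2 additive-genetic share of the liability variance.
#' @param spouse_share,sib_share,household_share shared-environment
#'   shares; together with `h2` they must not exceed 1 (the residual
#'   takes the remainder; total liability variance is 1).
#' @param rg cross-trait additive-genetic correlation.
#' @param r_spouse cross-trait correlation of the spouse-environment
#'   deviates.
#' @param grade_freq target population frequencies of grades 0-4 (used to
#'   place the thresholds); majority in grade 0.
#' @param thresholds optional explicit, strictly increasing liability
#'   cutpoints for the grades, overriding `grade_freq`.
#' @param prevalence_mdd population proportion of the binary trait.
#' @param fixed_effects list with `sex`, `age`, `age2` coefficients,
#'   applied to both liabilities.
#' @export
simulation_truth <- function(h2 = 0.4, spouse_share = 0.2, sib_share = 0,
                             household_share = 0, rg = 0.5, r_spouse = 0.5,
                             grade_freq = c(0.55, 0.15, 0.12, 0.10, 0.08),
                             thresholds = NULL,
                             prevalence_mdd = 0.12,
                             fixed_effects = list(sex = 0.3, age = 0.02,
                                                  age2 = -1e-4)) {
  shares <- c(h2, spouse_share, sib_share, household_share)
  stopifnot(all(shares >= 0), sum(shares) <= 1,
            abs(rg) <= 1, abs(r_spouse) <= 1,
            abs(sum(grade_freq) - 1) < 1e-8,
            prevalence_mdd > 0, prevalence_mdd < 1)
  if (!is.null(thresholds) && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  structure(list(var_additive = h2, var_spouse = spouse_share,
                 var_sib = sib_share, var_household = household_share,
                 var_residual = 1 - sum(shares),
                 h2 = h2, rg = rg, r_spouse = r_spouse,
                 grade_freq = grade_freq, thresholds = thresholds,
                 prevalence_mdd = prevalence_mdd,
                 fixed_effects = fixed_effects),
            class = "simulation_truth")
}

draw_offspring_n <- function(dist, n) {
  switch(dist$type,
         constant = rep(dist$k, n),
         poisson = stats::rpois(n, dist$lambda),
         stop("unknown offspring distribution type '", dist$type, "'"))
}

#' Simulate a multigenerational family cohort pedigree
#'
#' Each family starts from a founder couple; offspring of the middle
#' generations partner with immigrant founders at the design's couple
#' rate and reproduce, down to the requested depth. Couples are recorded
#' explicitly and households formed per the design rule. Deterministic
#' under a fixed seed.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A [pedigree].
#' @export
simulate_pedigree <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- list(id = list(), father = list(), mother = list(), sex = list(),
              couples = list(), hh_label = list(), hh_id = list())

  for (fam in seq_len(design$n_families)) {
    cnt <- 0L
    id <- character(0); father <- character(0); mother <- character(0)
    sex <- character(0)
    couples <- matrix(character(0), ncol = 2)
    hh_label <- character(0); hh_id <- character(0)
    new_id <- function() {
      cnt <<- cnt + 1L
      sprintf("f%04d_i%03d", fam, cnt)
    }
    add_person <- function(fa, mo, sx) {
      i <- new_id()
      id <<- c(id, i); father <<- c(father, fa); mother <<- c(mother, mo)
      sex <<- c(sex, sx)
      i
    }
    # generation 1: founder couple
    pa <- add_person(NA, NA, "male")
    ma <- add_person(NA, NA, "female")
    couples <- rbind(couples, c(pa, ma))
    gen_couples <- list(c(pa, ma))
    for (g in seq_len(design$generations - 1)) {
      next_couples <- list()
      for (cp in gen_couples) {
        noff <- draw_offspring_n(design$offspring_dist, 1)
        kids <- character(0)
        for (o in seq_len(noff)) {
          sx <- if (stats::runif(1) < 0.5) "female" else "male"
          kids <- c(kids, add_person(cp[1], cp[2], sx))
        }
        minors <- kids
        if (g < design$generations - 1) {
          for (k in kids) {
            if (stats::runif(1) < design$couple_rate) {
              sp_sex <- if (sex[match(k, id)] == "male") "female" else "male"
              sp <- add_person(NA, NA, sp_sex)
              couples <- rbind(couples, c(k, sp))
              next_couples[[length(next_couples) + 1]] <- c(k, sp)
              minors <- setdiff(minors, k)
            }
          }
        }
        if (design$household_rule == "couple_plus_minors") {
          members <- c(cp, minors)
          lab <- paste0("hh_", cp[1])
          hh_label <- c(hh_label, rep(lab, length(members)))
          hh_id <- c(hh_id, members)
        }
      }
      gen_couples <- next_couples
      if (!length(gen_couples)) break
    }
    acc$id[[fam]] <- id; acc$father[[fam]] <- father
    acc$mother[[fam]] <- mother; acc$sex[[fam]] <- sex
    acc$couples[[fam]] <- couples
    acc$hh_label[[fam]] <- hh_label; acc$hh_id[[fam]] <- hh_id
  }
  hh_id <- unlist(acc$hh_id)
  households <- if (length(hh_id))
    data.frame(household = unlist(acc$hh_label), id = hh_id)
  pedigree(unlist(acc$id), unlist(acc$father), unlist(acc$mother),
           unlist(acc$sex), couples = do.call(rbind, acc$couples),
           households = households)
}

#' Gene-drop breeding values through a pedigree
#'
#' Founders receive independent draws with the requested additive
#' variance (or 2x2 genetic covariance for two traits); each non-founder
#' is the mean of its parents' values plus a Mendelian-sampling deviate
#' with variance `0.5 * (1 - (F_f + F_m) / 2)` times the additive
#' (co)variance. An unknown parent is treated as a unique non-inbred
#' founder, contributing through the Mendelian variance.
#'
#' @param ped a [pedigree].
#' @param sigma scalar additive variance, or a 2x2 positive-semidefinite
#'   genetic covariance matrix for two traits.
#' @param nrep number of independent replicates (univariate only).
#' @param seed optional integer seed.
#' @param inbreeding optional precomputed inbreeding coefficients named
#'   by id (skips rebuilding the relationship matrix).
#' @return Named vector (scalar `sigma`, `nrep = 1`), matrix of `nrep`
#'   columns (univariate replicates), or an n x 2 matrix (bivariate).
#' @export
simulate_breeding_values <- function(ped, sigma, nrep = 1, seed = NULL,
                                     inbreeding = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == 2, ncol(sigma) == 2, nrep == 1)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("genetic covariance must be PSD")
    q <- 2L
    L <- chol_psd(sigma)
  } else {
    if (sigma < 0) stop("negative additive variance")
    q <- 1L
    L <- matrix(sqrt(sigma), 1, 1)
  }
  ord <- topological_order(ped)
  n <- length(ord)
  pos <- seq_len(n); names(pos) <- ord
  fi <- ifelse(is.na(ped$father), 0L, pos[ped$father])[match(ord, ped$id)]
  mi <- ifelse(is.na(ped$mother), 0L, pos[ped$mother])[match(ord, ped$id)]
  Fc <- if (is.null(inbreeding))
    inbreeding_coefficients(additive_relationship_matrix(ped))[ord]
  else inbreeding[ord]

  ncol_out <- q * nrep
  vals <- matrix(0, n, ncol_out)
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    if (f == 0L && m == 0L) {
      vals[i, ] <- as.vector(matrix(stats::rnorm(ncol_out), nrep, q) %*% L)
    } else {
      pmean <- 0
      d <- 1
      if (f > 0L && m > 0L) {
        pmean <- 0.5 * (vals[f, ] + vals[m, ])
        d <- 0.5 * (1 - (Fc[f] + Fc[m]) / 2)
      } else {
        p <- max(f, m)
        pmean <- 0.5 * vals[p, ]
        d <- 0.75 - 0.25 * Fc[p]
      }
      dev <- as.vector(matrix(stats::rnorm(ncol_out), nrep, q) %*%
                         (sqrt(d) * L))
      vals[i, ] <- pmean + dev
    }
  }
  rownames(vals) <- ord
  vals <- vals[ped$id, , drop = FALSE]
  if (q == 1L && nrep == 1L) stats::setNames(drop(vals), ped$id)
  else vals
}

chol_psd <- function(S) {
  ch <- suppressWarnings(tryCatch(chol(S), error = function(e) NULL))
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors))
}

# one shared deviate per group, identical for all members; bivariate
# version draws a correlated pair per group
group_deviates <- function(ped, groups, sigma2, cross_r = 0) {
  n <- length(ped$id)
  out <- matrix(0, n, 2)
  if (sigma2 <= 0 || !length(groups)) return(out)
  pos <- seq_len(n); names(pos) <- ped$id
  S <- sigma2 * matrix(c(1, cross_r, cross_r, 1), 2, 2)
  L <- chol_psd(S)
  for (g in groups) {
    d <- drop(stats::rnorm(2) %*% L)
    out[pos[g], 1] <- d[1]
    out[pos[g], 2] <- d[2]
  }
  # individuals outside every group get their own independent deviate
  ungrouped <- setdiff(ped$id, unlist(groups))
  if (length(ungrouped)) {
    d <- matrix(stats::rnorm(2 * length(ungrouped)), ncol = 2) %*% L
    out[pos[ungrouped], ] <- d
  }
  out
}

#' Simulate ordinal pain grades and binary depression status on a cohort
#'
#' Builds, per trait, a liability equal to fixed effects (sex, age, age
#' squared) plus a gene-dropped additive-genetic value plus one shared
#' deviate per couple / sibship / household group plus an independent
#' residual. The ordinal grade cuts the first liability at thresholds
#' matching the truth's target grade frequencies; the binary status
#' compares the second liability to its prevalence quantile. Ages are
#' uniform on 18-90 and sex is balanced.
#'
#' @param ped a [pedigree].
#' @param truth a [simulation_truth()].
#' @param seed optional integer seed.
#' @param inbreeding optional precomputed inbreeding coefficients named
#'   by id (useful when many phenotype replicates share one pedigree).
#' @return data.frame with `id`, `sex`, `age`, `cpg` (0-4), `mdd` (0/1).
#'   The generator's internals (genetic values, liabilities, thresholds)
#'   are attached as attribute `"internals"` for validation.
#' @export
simulate_phenotypes <- function(ped, truth, seed = NULL,
                                inbreeding = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(truth, "simulation_truth"))
  n <- length(ped$id)
  age <- stats::runif(n, 18, 90)
  sexnum <- as.numeric(ped$sex == "female")

  Sg <- truth$var_additive *
    matrix(c(1, truth$rg, truth$rg, 1), 2, 2)
  a <- if (truth$var_additive > 0)
    simulate_breeding_values(ped, Sg, inbreeding = inbreeding)
  else matrix(0, n, 2)

  spouse_groups <- apply(ped$couples, 1, c, simplify = FALSE)
  sp <- group_deviates(ped, spouse_groups, truth$var_spouse,
                       truth$r_spouse)
  sib <- group_deviates(ped, unname(ped$sibships), truth$var_sib)
  hh <- group_deviates(ped, unname(ped$households), truth$var_household)

  fe <- truth$fixed_effects
  xb <- fe$sex * sexnum + fe$age * age + fe$age2 * age^2
  e1 <- stats::rnorm(n, 0, sqrt(truth$var_residual))
  e2 <- stats::rnorm(n, 0, sqrt(truth$var_residual))
  liab1 <- xb + a[, 1] + sp[, 1] + sib[, 1] + hh[, 1] + e1
  liab2 <- xb + a[, 2] + sp[, 2] + sib[, 2] + hh[, 2] + e2

  thr <- if (!is.null(truth$thresholds)) truth$thresholds
  else {
    cum <- cumsum(truth$grade_freq)
    stats::quantile(liab1, cum[-length(cum)], names = FALSE)
  }
  if (any(diff(thr) <= 0))
    stop("grade thresholds are not strictly increasing")
  cpg <- findInterval(liab1, thr)
  thr_mdd <- stats::quantile(liab2, 1 - truth$prevalence_mdd,
                             names = FALSE)
  mdd <- as.integer(liab2 > thr_mdd)

  out <- data.frame(id = ped$id, sex = ped$sex, age = age,
                    cpg = cpg, mdd = mdd, stringsAsFactors = FALSE)
  attr(out, "internals") <- list(genetic = a, spouse = sp, sib = sib,
                                 household = hh,
                                 liability = cbind(liab1, liab2),
                                 thresholds = thr, thr_mdd = thr_mdd,
                                 truth = truth)
  out
}
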