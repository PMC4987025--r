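# Unit tests of the estimation machinery: REML backend, Gibbs backend,
# LRT/DIC arithmetic, proportions, stepwise selection mechanics.

test_that("REML matches the ANOVA expected-mean-squares solution on a balanced one-way design", {
  set.seed(41)
  ngroups <- 40; k <- 5
  g <- rep(seq_len(ngroups), each = k)
  u <- rnorm(ngroups, 0, sqrt(2))
  y <- u[g] + rnorm(ngroups * k, 0, sqrt(3))
  ids <- paste0("s", seq_along(y))
  # group-share structure built directly from the partition
  ped_stub <- pedigree(ids, rep(NA, length(y)), rep(NA, length(y)))
  hh <- data.frame(household = g, id = ids)
  ped_stub <- pedigree(ids, rep(NA, length(y)), rep(NA, length(y)),
                       households = hh)
  S <- group_covariance_matrix(ped_stub, "household_share")
  phen <- data.frame(id = ids, y = y)
  spec <- mixed_model_spec("y", "gaussian", fixed_effects = character(0),
                           random_components = "group")
  fit <- fit_reml(spec, phen, list(group = S))
  # closed-form ANOVA estimators for the balanced one-way layout
  ybar_g <- tapply(y, g, mean)
  msb <- k * sum((ybar_g - mean(y))^2) / (ngroups - 1)
  msw <- sum((y - ybar_g[g])^2) / (ngroups * (k - 1))
  expect_equal(unname(fit$estimates["residual"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["group"]), (msb - msw) / k,
               tolerance = 1e-6)
})

test_that("REML shrinks the additive component to zero on pure-noise data", {
  cohort <- test_cohort(n_families = 120, seed = 51,
                        truth = simulation_truth(h2 = 0, spouse_share = 0))
  phen <- cohort$phen
  phen$noise <- rnorm(nrow(phen))
  spec <- mixed_model_spec("noise", "gaussian",
                           random_components = "additive")
  fit <- fit_reml(spec, phen, cohort$structures)
  expect_lt(fit$proportions$proportion[1], 0.1)
  expect_equal(sum(fit$proportions$proportion), 1, tolerance = 1e-8)
})

test_that("REML recovers h2 = 0.5 from unrelated sibships of four", {
  # 200 families x 4 observed sibs (parents unphenotyped), truth h2 = 0.5
  hats <- vapply(1:20, function(s) {
    nf <- 200
    fam <- rep(seq_len(nf), each = 6)
    pos <- rep(1:6, nf)
    id <- sprintf("f%03d_%d", fam, pos)
    father <- ifelse(pos <= 2, NA, sprintf("f%03d_1", fam))
    mother <- ifelse(pos <= 2, NA, sprintf("f%03d_2", fam))
    ped <- pedigree(id, father, mother,
                    sex = rep(c("male", "female", "female", "male",
                                "female", "male"), nf))
    a <- simulate_breeding_values(ped, 0.5, seed = 700 + s)
    set.seed(800 + s)
    y <- a + rnorm(length(a), 0, sqrt(0.5))
    phen <- data.frame(id = ped$id, y = as.numeric(y))
    # keep offspring only: parents unobserved, sibs share A = 0.5
    phen <- phen[pos > 2, ]
    spec <- mixed_model_spec("y", "gaussian",
                             fixed_effects = character(0),
                             random_components = "additive")
    fit <- fit_reml(spec, phen,
                    list(additive = additive_relationship_matrix(ped)))
    fit$proportions$proportion[1]
  }, numeric(1))
  expect_lt(abs(mean(hats) - 0.5), 0.05)
})

test_that("likelihood-ratio and z arithmetic match the chi-squared and normal oracles", {
  expect_equal(likelihood_ratio_test(0, 0, df = 1)$statistic, 0)
  expect_equal(likelihood_ratio_test(0, 0, df = 1)$p_value, 1)
  lrt <- likelihood_ratio_test(2, 0, df = 1)
  expect_equal(lrt$statistic, 4)
  expect_equal(lrt$p_value, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(lrt$p_value, 4), 0.0455)
  lrtb <- likelihood_ratio_test(2, 0, df = 1, boundary = TRUE)
  expect_equal(lrtb$p_value, 0.5 * pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(likelihood_ratio_test(-1, 0), "nested")
  expect_equal(likelihood_ratio_test(40 / 2, 0, df = 1)$p_value,
               pchisq(40, 1, lower.tail = FALSE))
})

test_that("DIC arithmetic matches its definition on hand-built chains", {
  # constant deviance: p_D = 0, DIC = the constant
  expect_equal(dic(list(deviance_trace = rep(7.5, 100),
                        deviance_at_means = 7.5)), 7.5)
  # mean 11, deviance at means 9: DIC = 11 + (11 - 9) = 13
  expect_equal(dic(list(deviance_trace = c(10, 12),
                        deviance_at_means = 9)), 13)
  expect_error(dic(list()), "deviance")
})

test_that("variance proportions normalize and reproduce the reported decomposition", {
  p <- variance_proportions(c(additive = 0.384, spouse = 0.187,
                              residual = 0.429))
  expect_equal(p$proportion, c(0.384, 0.187, 0.429), tolerance = 1e-12)
  expect_equal(sum(p$proportion), 1)
  p1 <- variance_proportions(c(residual = 3.3))
  expect_equal(p1$proportion, 1)
  expect_error(variance_proportions(c(a = 0, b = 0)), "zero total")
  set.seed(61)
  for (i in 1:20) {
    v <- runif(4)
    expect_equal(sum(variance_proportions(setNames(v, letters[1:4]))$proportion), 1)
  }
})

test_that("Gibbs sampler recovers a null and a strong binary heritability", {
  cohort <- test_cohort(n_families = 150, seed = 71,
                        truth = simulation_truth(h2 = 0, spouse_share = 0,
                                                 prevalence_mdd = 0.3))
  spec <- mixed_model_spec("mdd", "binary", random_components = "additive",
                           mcmc_control = mcmc_profile("fast", chains = 1))
  set.seed(72)
  fit0 <- suppressWarnings(fit_gibbs_ordinal(spec, cohort$phen,
                                             cohort$structures))
  expect_lt(fit0$proportions$lower[1], 0.05)

  # ordinal response with an absent category is refused
  phen_bad <- cohort$phen
  phen_bad$cpg[phen_bad$cpg == 2] <- 3
  spec_o <- mixed_model_spec("cpg", "ordinal",
                             random_components = "additive",
                             mcmc_control = mcmc_profile("fast", chains = 1))
  expect_error(suppressWarnings(
    fit_gibbs_ordinal(spec_o, phen_bad, cohort$structures)),
    "zero observations")
})

test_that("stepwise selection keeps a real spouse effect and reports a full trace", {
  cohort <- test_cohort(n_families = 250, seed = 81,
                        truth = simulation_truth(h2 = 0.4,
                                                 spouse_share = 0.25))
  phen <- cohort$phen
  phen$liab <- attr(cohort$phen, "internals")$liability[, 1]
  spec <- mixed_model_spec("liab", "gaussian",
                           random_components = "additive")
  sel <- suppressWarnings(
    stepwise_model_selection(spec, phen, cohort$structures,
                             candidates = c("spouse", "sib"),
                             criterion = "LRT"))
  expect_true("spouse" %in% sel$selected)
  expect_true(all(c("additive", "additive+spouse") %in% sel$trace$model))
  # trace retains every model examined with its criterion value
  expect_true(all(is.finite(sel$trace$value)))
})
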