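# Bivariate genetic/environmental correlation machinery.

make_bivar_cohort <- function(n_families, seed, rg = 0.5, r_spouse = 0.5,
                              h2 = 0.4, spouse_share = 0.2) {
  ped <- simulate_pedigree(cohort_design(n_families = n_families),
                           seed = seed)
  truth <- simulation_truth(h2 = h2, spouse_share = spouse_share,
                            rg = rg, r_spouse = r_spouse)
  phen <- simulate_phenotypes(ped, truth, seed = seed + 5000)
  list(ped = ped, phen = phen,
       structures = list(additive = additive_relationship_matrix(ped),
                         spouse = group_covariance_matrix(ped,
                                                          "spouse_share")))
}

test_that("a duplicated trait yields unit correlations everywhere", {
  co <- make_bivar_cohort(120, seed = 91)
  phen <- co$phen
  phen$cpg2 <- phen$cpg
  fit <- suppressWarnings(
    fit_bivariate_reml(phen, c("cpg", "cpg2"), co$structures))
  ok <- is.finite(fit$correlations$correlation)
  expect_true(all(abs(fit$correlations$correlation[ok] - 1) < 1e-3))
  expect_equal(fit$r_phenotypic, 1, tolerance = 1e-4)
})

test_that("component cross-covariances sum to the phenotypic covariance and are order-symmetric", {
  co <- make_bivar_cohort(150, seed = 92)
  fit <- fit_bivariate_reml(co$phen, c("cpg", "mdd"), co$structures)
  total_cross <- sum(vapply(fit$blocks, function(b) b[1, 2], numeric(1)))
  v1 <- sum(vapply(fit$blocks, function(b) b[1, 1], numeric(1)))
  v2 <- sum(vapply(fit$blocks, function(b) b[2, 2], numeric(1)))
  expect_equal(fit$r_phenotypic, total_cross / sqrt(v1 * v2),
               tolerance = 1e-8)

  fit_rev <- fit_bivariate_reml(co$phen, c("mdd", "cpg"), co$structures)
  expect_equal(fit_rev$correlations$correlation,
               fit$correlations$correlation, tolerance = 1e-3)
  expect_equal(fit_rev$r_phenotypic, fit$r_phenotypic, tolerance = 1e-3)
})

test_that("constrained fits are nested and drive the correlation tests", {
  co <- make_bivar_cohort(200, seed = 93)
  full <- fit_bivariate_reml(co$phen, c("cpg", "mdd"), co$structures)
  null_g <- constrained_fit(co$phen, c("cpg", "mdd"), co$structures,
                            constraint = "rg")
  null_e <- constrained_fit(co$phen, c("cpg", "mdd"), co$structures,
                            constraint = "r_env")
  expect_lte(null_g$log_likelihood, full$log_likelihood + 1e-6)
  expect_lte(null_e$log_likelihood, full$log_likelihood + 1e-6)
  expect_equal(null_g$correlations$correlation[
    null_g$correlations$component == "additive"], 0)
  lrt <- correlation_significance(full, null_g)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$statistic, 0)
  expect_error(fit_bivariate_reml(co$phen, c("cpg", "mdd"),
                                  co$structures,
                                  constraint = "nonsense"),
               "unknown constraint")
  # no shared environment in the model: r_env constraint is refused
  expect_error(constrained_fit(co$phen, c("cpg", "mdd"),
                               co$structures["additive"],
                               constraint = "r_env"),
               "no shared-environment")
})

test_that("adjusted phenotypic correlation z-test matches the normal oracle", {
  fake <- structure(list(r_phenotypic = 0.2, r_phenotypic_se = 0.1,
                         pearson = 0.21), class = "bivar_fit")
  res <- adjusted_phenotypic_correlation(fake)
  expect_equal(res$z, 2)
  expect_equal(res$p_value, 2 * pnorm(2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.0455)
  fake0 <- structure(list(r_phenotypic = 0, r_phenotypic_se = 0.1,
                          pearson = 0), class = "bivar_fit")
  expect_equal(adjusted_phenotypic_correlation(fake0)$p_value, 1)
})

test_that("independent traits give a genetic correlation near zero", {
  co <- make_bivar_cohort(250, seed = 94, rg = 0, r_spouse = 0)
  fit <- fit_bivariate_reml(co$phen, c("cpg", "mdd"), co$structures)
  rg_row <- fit$correlations[fit$correlations$component == "additive", ]
  expect_lt(abs(rg_row$correlation), 2.5 * rg_row$se + 0.05)
})

test_that("missing one trait for part of the cohort is handled pairwise-complete", {
  co <- make_bivar_cohort(150, seed = 95)
  phen <- co$phen
  drop_idx <- sample(nrow(phen), 200)
  phen$mdd[drop_idx] <- NA
  fit <- suppressWarnings(
    fit_bivariate_reml(phen, c("cpg", "mdd"), co$structures))
  expect_equal(fit$n_trait1, nrow(phen))
  expect_equal(fit$n_trait2, nrow(phen) - 200)
  expect_equal(fit$n_both, nrow(phen) - 200)
  expect_true(is.finite(fit$log_likelihood))
})
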