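test_that("simulated pedigrees have the designed shape and are reproducible", {
  des <- cohort_design(n_families = 10, generations = 2,
                       offspring_dist = list(type = "constant", k = 2))
  ped <- simulate_pedigree(des, seed = 4)
  expect_length(ped$id, 40) # 10 x (2 founders + 2 offspring)
  expect_equal(nrow(ped$couples), 10)
  ped2 <- simulate_pedigree(des, seed = 4)
  expect_identical(ped, ped2)

  # deeper pedigrees agree with the coancestry oracle
  des5 <- cohort_design(n_families = 2, generations = 5,
                        offspring_dist = list(type = "constant", k = 2),
                        couple_rate = 1)
  ped5 <- simulate_pedigree(des5, seed = 5)
  A <- additive_relationship_matrix(ped5)
  Ao <- kinship_oracle(ped5)
  expect_equal(as.matrix(A$matrix)[ped5$id, ped5$id], Ao,
               tolerance = 1e-12, ignore_attr = TRUE)
  # great-grandparent relatedness present: family-1 founder vs the last
  # family-1 descendant (three meioses away or more)
  fam1 <- grep("^f0001", ped5$id, value = TRUE)
  deepest <- fam1[max(which(!is.na(ped5$father[match(fam1, ped5$id)])))]
  expect_gt(Ao["f0001_i001", deepest], 0)
  expect_lt(Ao["f0001_i001", deepest], 0.5)
})

test_that("gene dropping: degenerate and bivariate contracts", {
  ped <- random_pedigree(max_members = 12, seed = 21)
  expect_equal(unname(simulate_breeding_values(ped, 0, seed = 1)),
               rep(0, length(ped$id)))
  expect_error(simulate_breeding_values(ped, -1), "negative")
  # rg = 1 with equal variances: identical trait values
  S <- matrix(c(1, 1, 1, 1), 2, 2)
  v <- simulate_breeding_values(ped, S, seed = 2)
  expect_equal(v[, 1], v[, 2], tolerance = 1e-12)
})

test_that("gene-dropped values reproduce sigma2_a * A on a fixed pedigree", {
  ped <- pedigree(paste0("i", 1:10),
                  c(NA, NA, "i1", "i1", NA, "i3", "i3", NA, "i6", "i6"),
                  c(NA, NA, "i2", "i2", NA, "i5", "i5", NA, "i8", "i8"))
  s2 <- 2.5
  nrep <- 4000
  vals <- simulate_breeding_values(ped, s2, nrep = nrep, seed = 33)
  emp <- stats::cov(t(vals))
  A <- s2 * as.matrix(additive_relationship_matrix(ped)$matrix)[ped$id,
                                                                ped$id]
  # entrywise Monte-Carlo standard error of a covariance estimate
  mc_se <- sqrt((outer(diag(A), diag(A)) + A^2) / nrep)
  expect_true(all(abs(emp - A) <= 3.5 * mc_se))
})

test_that("phenotype generator respects thresholds, prevalence and shares", {
  ped <- simulate_pedigree(cohort_design(n_families = 400), seed = 6)
  truth <- simulation_truth()
  phen <- simulate_phenotypes(ped, truth, seed = 7)
  expect_true(all(phen$cpg %in% 0:4))
  expect_true(all(phen$mdd %in% 0:1))
  expect_equal(mean(phen$mdd), truth$prevalence_mdd, tolerance = 0.01)
  expect_equal(as.numeric(table(phen$cpg) / nrow(phen)),
               truth$grade_freq, tolerance = 0.02)
  expect_true(all(phen$age >= 18 & phen$age <= 90))

  # degenerate thresholds collapse every grade to the same category
  t0 <- simulation_truth(h2 = 0, spouse_share = 0,
                         thresholds = c(1e6, 2e6, 3e6, 4e6))
  p0 <- simulate_phenotypes(ped, t0, seed = 8)
  expect_equal(unique(p0$cpg), 0)
  expect_error(simulation_truth(thresholds = c(1, 1, 2, 3)),
               "strictly increasing")

  # cross-trait genetic correlation close to its target
  big <- simulate_pedigree(cohort_design(n_families = 1200), seed = 9)
  ph <- simulate_phenotypes(big, simulation_truth(rg = 0.5), seed = 10)
  a <- attr(ph, "internals")$genetic
  expect_equal(stats::cor(a[, 1], a[, 2]), 0.5, tolerance = 0.05)
})

test_that("spouse-shared environment induces excess spouse concordance", {
  ped <- simulate_pedigree(cohort_design(n_families = 700), seed = 16)
  truth <- simulation_truth(h2 = 0.4, spouse_share = 0.2)
  phen <- simulate_phenotypes(ped, truth, seed = 17)
  g <- phen$cpg
  names(g) <- phen$id
  pairs <- ped$couples
  r_sp <- stats::cor(g[pairs[, 1]], g[pairs[, 2]])
  # permutation null: random re-pairings of the same individuals
  set.seed(18)
  r_null <- replicate(200, {
    sh <- sample(pairs[, 2])
    stats::cor(g[pairs[, 1]], g[sh])
  })
  expect_gt(r_sp, stats::quantile(r_null, 0.99))
})

test_that("liability variance decomposition matches the declared truth", {
  ped <- simulate_pedigree(cohort_design(n_families = 1200), seed = 26)
  truth <- simulation_truth(h2 = 0.4, spouse_share = 0.2)
  phen <- simulate_phenotypes(ped, truth, seed = 27)
  int <- attr(phen, "internals")
  expect_equal(stats::var(int$genetic[, 1]), 0.4, tolerance = 0.04)
  expect_equal(stats::var(int$spouse[, 1]), 0.2, tolerance = 0.02)
  # residual = liability minus all modelled parts (fixed effects included)
  fe <- truth$fixed_effects
  xb <- fe$sex * (phen$sex == "female") + fe$age * phen$age +
    fe$age2 * phen$age^2
  resid <- int$liability[, 1] - xb - int$genetic[, 1] - int$spouse[, 1] -
    int$sib[, 1] - int$household[, 1]
  expect_equal(stats::var(resid), truth$var_residual, tolerance = 0.03)
})

test_that("cohort files round-trip through the TSV writers", {
  ped <- simulate_pedigree(cohort_design(n_families = 15), seed = 36)
  truth <- simulation_truth()
  phen <- simulate_phenotypes(ped, truth, seed = 37)
  dir <- tempfile()
  paths <- write_cohort(ped, phen, truth, dir)
  ped2 <- parse_pedigree(paths["pedigree"], paths["couples"],
                         paths["households"])
  expect_equal(ped2$id, ped$id)
  expect_equal(ped2$father, ped$father)
  expect_equal(sort(unlist(ped2$households)), sort(unlist(ped$households)))
  expect_equal(nrow(ped2$couples), nrow(ped$couples))
  phen2 <- utils::read.delim(paths["phenotypes"])
  expect_equal(phen2$cpg, phen$cpg)
  tr <- yaml::read_yaml(paths["truth"])
  expect_equal(tr$h2, truth$h2)
})
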