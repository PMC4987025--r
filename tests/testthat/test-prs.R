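# Polygenic scoring: readers, allele alignment, thresholding, PCA,
# association and variance explained.

write_sumstats <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("summary-statistics reader validates structure and ranges", {
  good <- data.frame(SNP = paste0("rs", 1:4), A1 = c("A", "C", "G", "T"),
                     A2 = c("C", "A", "T", "G"),
                     BETA = c(0.1, -0.2, 0, 0.05),
                     P = c(0.001, 0.5, 1, 0.03))
  st <- read_summary_stats(write_sumstats(good))
  expect_s3_class(st, "summary_stats")
  expect_equal(nrow(st), 4)

  dup <- good; dup$SNP[2] <- "rs1"
  expect_error(read_summary_stats(write_sumstats(dup)), "rs1")
  p0 <- good; p0$P[1] <- 0
  expect_error(read_summary_stats(write_sumstats(p0)), "0, 1")
  nocol <- good[, -4]
  expect_error(read_summary_stats(write_sumstats(nocol)), "BETA")
})

test_that("VCF writer/reader round-trips dosages, missing entries included", {
  ped <- simulate_pedigree(cohort_design(n_families = 6, generations = 2),
                           seed = 101)
  gwas <- gwas_truth(n_snps = 30, n_causal = 10, seed = 102)
  geno <- simulate_target_genotypes(ped, gwas, seed = 103,
                                    missing_rate = 0.05)
  f <- tempfile(fileext = ".vcf")
  write_vcf(geno, f)
  geno2 <- read_genotypes(f, "vcf")
  expect_equal(geno2$ids, geno$ids)
  expect_equal(geno2$dosages, geno$dosages, ignore_attr = TRUE)
  expect_equal(geno2$snps$counted_allele, geno$snps$counted_allele)

  # byte-identical rewrite under the same seed
  geno_b <- simulate_target_genotypes(ped, gwas, seed = 103,
                                      missing_rate = 0.05)
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(geno_b, f2)
  expect_identical(readLines(f), readLines(f2))

  # dosage TSV round-trip
  f3 <- tempfile(fileext = ".tsv")
  write_dosage_tsv(geno, f3)
  geno3 <- read_genotypes(f3, "dosage_tsv")
  expect_equal(geno3$dosages, geno$dosages, ignore_attr = TRUE)

  # malformed line reported with its line number
  lines <- readLines(f)
  lines[12] <- paste(strsplit(lines[12], "\t")[[1]][1:5], collapse = "\t")
  writeLines(lines, f)
  expect_error(read_genotypes(f, "vcf"), "line 12")
})

test_that("VCF output is readable by an independent VCF parser", {
  skip_if_not_installed("vcfR")
  ped <- simulate_pedigree(cohort_design(n_families = 4, generations = 2),
                           seed = 111)
  gwas <- gwas_truth(n_snps = 12, n_causal = 4, seed = 112)
  geno <- simulate_target_genotypes(ped, gwas, seed = 113)
  f <- tempfile(fileext = ".vcf")
  write_vcf(geno, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  gt <- vcfR::extract.gt(v, as.numeric = FALSE)
  dos_oracle <- matrix(c(`0/0` = 0, `0/1` = 1, `1/1` = 2)[gt],
                       nrow(gt), ncol(gt))
  expect_equal(unname(t(dos_oracle)), unname(geno$dosages))
})

test_that("allele alignment keeps, flips, and excludes correctly", {
  stats <- structure(data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5"),
    effect_allele = c("A", "A", "A", "A", "A"),
    other_allele = c("C", "C", "T", "C", "C"),
    weight = c(0.5, 0.5, 0.5, 0.5, 0.5),
    p_value = rep(0.01, 5), stringsAsFactors = FALSE),
    class = c("summary_stats", "data.frame"))
  geno <- structure(list(
    ids = c("x", "y"),
    snps = data.frame(
      snp_id = c("s1", "s2", "s3", "s4", "s6"),
      counted_allele = c("A", "C", "A", "T", "A"),
      other_allele = c("C", "A", "T", "G", "C"),
      stringsAsFactors = FALSE),
    dosages = matrix(1, 2, 5, dimnames = list(c("x", "y"),
                                              c("s1", "s2", "s3", "s4",
                                                "s6")))),
    class = "genotype_matrix")
  al <- align_alleles(stats, geno)
  expect_equal(unname(al$weights["s1"]), 0.5)   # same orientation
  expect_equal(unname(al$weights["s2"]), -0.5)  # swapped: sign flips
  expect_false("s3" %in% names(al$weights))     # A/T ambiguous
  expect_equal(al$exclusions$reason[al$exclusions$snp == "s3"],
               "strand-ambiguous")
  expect_equal(unname(al$weights["s4"]), 0.5)   # strand flip, same orient
  expect_true(all(names(al$weights) %in% c("s1", "s2", "s4")))
  geno$snps$snp_id <- paste0("z", 1:5)
  colnames(geno$dosages) <- geno$snps$snp_id
  expect_error(align_alleles(stats, geno), "no overlapping")
})

test_that("scores are flip-invariant and SNP-monotone over thresholds", {
  ped <- simulate_pedigree(cohort_design(n_families = 40), seed = 121)
  gwas <- gwas_truth(n_snps = 120, n_causal = 40, n_train = 4000,
                     seed = 122)
  geno <- simulate_target_genotypes(ped, gwas, seed = 123)
  ss <- simulate_training_gwas(gwas, seed = 124)
  stats <- read_summary_stats(write_sumstats(ss))
  prof <- threshold_and_score(stats, geno)
  expect_true(all(diff(prof$n_snps_used) >= 0))
  for (nm in grep("_std$", names(prof$scores), value = TRUE)) {
    expect_equal(mean(prof$scores[[nm]]), 0, tolerance = 1e-10)
    expect_equal(sd(prof$scores[[nm]]), 1, tolerance = 1e-10)
  }

  # artificially relabel one SNP's alleles (swap + negate weight): the
  # scores must not change
  ss2 <- ss
  ss2$A1[5] <- ss$A2[5]; ss2$A2[5] <- ss$A1[5]; ss2$BETA[5] <- -ss$BETA[5]
  prof2 <- threshold_and_score(read_summary_stats(write_sumstats(ss2)),
                               geno)
  expect_equal(prof2$scores, prof$scores, tolerance = 1e-12)

  # SNP reordering leaves the scores unchanged
  ss3 <- ss[sample(nrow(ss)), ]
  prof3 <- threshold_and_score(read_summary_stats(write_sumstats(ss3)),
                               geno)
  expect_equal(prof3$scores[, sort(names(prof3$scores))],
               prof$scores[, sort(names(prof$scores))], tolerance = 1e-12)
})

test_that("threshold counting and score arithmetic follow the definitions", {
  geno <- structure(list(
    ids = c("a", "b"),
    snps = data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                      counted_allele = rep("A", 4),
                      other_allele = rep("C", 4),
                      stringsAsFactors = FALSE),
    dosages = matrix(c(2, 1, 1, 0, 0, 2, 1, 1), 2, 4,
                     dimnames = list(c("a", "b"),
                                     c("s1", "s2", "s3", "s4")))),
    class = "genotype_matrix")
  stats <- structure(data.frame(
    snp = c("s1", "s2", "s3", "s4"),
    effect_allele = rep("A", 4), other_allele = rep("C", 4),
    weight = c(0.2, -0.1, 0.3, 0.4),
    p_value = c(0.001, 0.03, 0.2, 0.6), stringsAsFactors = FALSE),
    class = c("summary_stats", "data.frame"))
  prof <- threshold_and_score(stats, geno,
                              thresholds = c(0.05, 0.5))
  expect_equal(unname(prof$n_snps_used), c(2L, 3L))
  # raw score at pT = 0.05 for individual a: 0.2*2 + (-0.1)*1 = 0.3
  expect_equal(prof$scores$pT_0.05[1], 0.3)
})

test_that("missing dosages are mean-imputed with zero SD contribution", {
  geno <- structure(list(
    ids = paste0("i", 1:4),
    snps = data.frame(snp_id = c("s1", "s2"),
                      counted_allele = rep("A", 2),
                      other_allele = rep("C", 2),
                      stringsAsFactors = FALSE),
    dosages = matrix(c(0, 1, 2, 1, NA, NA, NA, NA), 4, 2,
                     dimnames = list(paste0("i", 1:4), c("s1", "s2")))),
    class = "genotype_matrix")
  stats <- structure(data.frame(
    snp = c("s1", "s2"), effect_allele = rep("A", 2),
    other_allele = rep("C", 2), weight = c(0.5, 1),
    p_value = c(0.01, 0.01), stringsAsFactors = FALSE),
    class = c("summary_stats", "data.frame"))
  prof <- threshold_and_score(stats, geno, thresholds = 0.05)
  # s2 all-missing: imputed dosage = NaN frequency -> dropped from mean;
  # but partial missing uses 2 * freq
  expect_equal(stats::sd(prof$scores$pT_0.05 - 0.5 * c(0, 1, 2, 1)), 0,
               tolerance = 1e-12)
})

test_that("ancestry components separate simulated subpopulations", {
  set.seed(131)
  n <- 120; m <- 150
  pop <- rep(0:1, each = n / 2)
  maf <- cbind(runif(m, 0.1, 0.3), runif(m, 0.5, 0.9))
  dos <- t(vapply(seq_len(n), function(i)
    rbinom(m, 2, maf[, pop[i] + 1]), numeric(m)))
  geno <- structure(list(ids = paste0("i", 1:n),
                         snps = data.frame(snp_id = paste0("s", 1:m),
                                           counted_allele = "A",
                                           other_allele = "C"),
                         dosages = dos), class = "genotype_matrix")
  pcs <- ancestry_components(geno, k = 4)
  expect_equal(dim(pcs), c(n, 4))
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  expect_equal(ncol(ancestry_components(geno, k = 0)), 0)
  expect_error(ancestry_components(geno, k = 1000), "exceeds")
})

test_that("variance explained follows beta^2 Var(score) / Var(y)", {
  score <- rnorm(500); y <- rnorm(500, sd = 2)
  expect_equal(prs_variance_explained(0.1, scale(score)[, 1] * 1, y),
               0.1^2 * var(scale(score)[, 1]) / var(y))
  expect_equal(prs_variance_explained(0, score, y), 0)
  expect_error(prs_variance_explained(0.1, score, rep(1, 500)),
               "zero phenotype variance")
  # worked numbers: beta 0.1, Var(score) 1, Var(y) 4 -> 0.0025
  s <- rnorm(2000); s <- (s - mean(s)) / sd(s)
  y4 <- rnorm(2000, sd = 2)
  y4 <- (y4 - mean(y4)) / sd(y4) * 2
  expect_equal(prs_variance_explained(0.1, s, y4), 0.0025,
               tolerance = 1e-10)
})

test_that("null scores show calibrated association under relatedness adjustment", {
  ped <- simulate_pedigree(cohort_design(n_families = 100), seed = 141)
  truth <- simulation_truth()
  phen <- simulate_phenotypes(ped, truth, seed = 142)
  A <- additive_relationship_matrix(ped)
  set.seed(143)
  score <- stats::setNames(rnorm(length(ped$id)), ped$id)
  res <- prs_mixed_association(score, phen, "cpg", structure = A)
  expect_true(abs(res$beta) < 2.5 * (res$upper - res$beta) / 1.96 + 0.05)
  expect_true(res$variance_explained >= 0 && res$variance_explained <= 1)
  expect_error(prs_mixed_association(stats::setNames(rep(1, length(ped$id)),
                                                     ped$id),
                                     phen, "cpg", structure = A),
               "constant")
})
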