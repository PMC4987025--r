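#' Configuration of an end-to-end family study
#'
#' Either a simulation block (design + truth + GWAS truth) or explicit
#' input paths per data role. Seeds are explicit; every stage derives its
#' randomness from `seed`.
#'
#' @param simulation list with `design` ([cohort_design()]), `truth`
#'   ([simulation_truth()]) and optionally `gwas` ([gwas_truth()]); or
#'   `NULL` when `paths` are given.
#' @param paths named list of input files (`pedigree`, `phenotypes`,
#'   `couples`, `households`, `summary_stats`, `genotypes`); or `NULL`.
#' @param backend `"reml"`, `"gibbs"` or `"both"` for the univariate
#'   stage.
#' @param criterion stepwise selection criterion, `"LRT"` or `"DIC"`.
#' @param thresholds PRS p-value thresholds.
#' @param mcmc_profile `"fast"` or `"paper"`.
#' @param seed integer master seed.
#' @param outdir output directory for reports, or `NULL` to skip writing.
#' @export
study_config <- function(simulation = NULL, paths = NULL,
                         backend = c("both", "reml", "gibbs"),
                         criterion = c("LRT", "DIC"),
                         thresholds = c(0.01, 0.05, 0.1, 0.5),
                         mcmc_profile = c("fast", "paper"),
                         seed = 1, outdir = NULL) {
  if (is.null(simulation) == is.null(paths))
    stop("exactly one of 'simulation' or 'paths' must be given")
  structure(list(simulation = simulation, paths = paths,
                 backend = match.arg(backend),
                 criterion = match.arg(criterion),
                 thresholds = thresholds,
                 mcmc_profile = match.arg(mcmc_profile),
                 seed = seed, outdir = outdir),
            class = "study_config")
}

config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(lapply(unclass(config)[c("backend", "criterion", "thresholds",
                                   "mcmc_profile", "seed")], unclass),
          tmp)
  unname(tools::md5sum(tmp))
}

# assemble pedigree + phenotypes + structures from either config branch
load_study_data <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    ped <- simulate_pedigree(sim$design, seed = config$seed)
    phen <- simulate_phenotypes(ped, sim$truth, seed = config$seed + 1e6)
  } else {
    ped <- parse_pedigree(config$paths$pedigree, config$paths$couples,
                          config$paths$households)
    phen <- utils::read.delim(config$paths$phenotypes,
                              stringsAsFactors = FALSE)
    phen$id <- as.character(phen$id)
  }
  structures <- list(additive = additive_relationship_matrix(ped),
                     spouse = group_covariance_matrix(ped, "spouse_share"),
                     sib = group_covariance_matrix(ped, "sib_share"),
                     household = group_covariance_matrix(ped,
                                                         "household_share"))
  list(ped = ped, phenotypes = phen, structures = structures)
}

report_header <- function(config, stage) {
  c(paste0("# famvc ", as.character(utils::packageVersion("famvc")),
           " | stage: ", stage),
    paste0("# seed: ", config$seed, " | config: ",
           config_fingerprint(config)))
}

write_report <- function(lines, table, config, stage) {
  if (is.null(config$outdir)) return(invisible(NULL))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$outdir, paste0(stage, ".tsv"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(report_header(config, stage), lines), con)
  suppressWarnings(utils::write.table(table, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Univariate stage: variance decomposition with stepwise selection
#'
#' Builds the additive and shared-environment structures, runs the
#' stepwise component selection from the additive-only base model, and
#' reports the full model-comparison table plus the selected model's
#' variance proportions with 95% intervals.
#'
#' @param config a [study_config()].
#' @return list with `selection` (trace + winner), `fit`, `proportions`,
#'   and the data used.
#' @export
run_univariate <- function(config) {
  set.seed(config$seed)
  dat <- load_study_data(config)
  spec <- mixed_model_spec("cpg",
                           scale = if (config$criterion == "DIC")
                             "ordinal" else "gaussian",
                           random_components = "additive",
                           mcmc_control = mcmc_profile(
                             config$mcmc_profile,
                             chains = if (config$mcmc_profile == "fast")
                               1 else 3))
  sel <- stepwise_model_selection(spec, dat$phenotypes, dat$structures,
                                  candidates = c("spouse", "sib",
                                                 "household"),
                                  criterion = config$criterion)
  props <- variance_proportions(sel$best_fit)
  write_report(paste0("# selected: ",
                      paste(sel$selected, collapse = "+")),
               sel$trace, config, "univariate")
  list(selection = sel, fit = sel$best_fit, proportions = props,
       data = dat)
}

#' Bivariate stage: partition the pain-depression covariance
#'
#' Fits the full bivariate model (additive + retained shared environment
#' + residual), the two constrained nulls, and reports the genetic,
#' shared-environment and adjusted phenotypic correlations with SEs and
#' likelihood-ratio p-values.
#'
#' @param config a [study_config()].
#' @param components random components to carry into the bivariate model
#'   (default: additive + spouse, the univariate winner's shape); pass
#'   the `selected` element of [run_univariate()] to chain the stages.
#' @export
run_bivariate <- function(config, components = c("additive", "spouse")) {
  set.seed(config$seed)
  dat <- load_study_data(config)
  structures <- dat$structures[intersect(components,
                                         names(dat$structures))]
  null_g <- fit_bivariate_reml(dat$phenotypes, c("cpg", "mdd"), structures,
                               constraint = "rg")
  null_e <- NULL
  if (length(setdiff(names(structures), "additive")))
    null_e <- fit_bivariate_reml(dat$phenotypes, c("cpg", "mdd"),
                                 structures, constraint = "r_env")
  # warm-start the full model from the better-fitting null so the
  # likelihood-ratio comparisons stay nested
  best_null <- if (!is.null(null_e) &&
                     null_e$log_likelihood > null_g$log_likelihood)
    null_e else null_g
  full <- fit_bivariate_reml(dat$phenotypes, c("cpg", "mdd"), structures,
                             init = best_null$estimates)
  lrt_g <- correlation_significance(full, null_g)
  lrt_e <- if (!is.null(null_e)) correlation_significance(full, null_e)
  phen_cor <- adjusted_phenotypic_correlation(full)
  tab <- full$correlations
  tab$lrt_p <- NA_real_
  tab$lrt_p[tab$component == "additive"] <- lrt_g$p_value
  if (!is.null(lrt_e)) {
    envc <- setdiff(names(structures), "additive")[1]
    tab$lrt_p[tab$component == envc] <- lrt_e$p_value
  }
  tab <- rbind(tab, data.frame(component = "phenotypic",
                               correlation = phen_cor$estimate,
                               se = phen_cor$se, constrained = FALSE,
                               lrt_p = phen_cor$p_value))
  write_report(character(0), tab, config, "bivariate")
  list(fit = full, correlations = tab, lrt_genetic = lrt_g,
       lrt_environment = lrt_e, phenotypic = phen_cor, data = dat)
}

#' Polygenic-score stage: cross-prediction at p-value thresholds
#'
#' Simulates (or loads) the training GWAS and target genotypes, scores
#' the target cohort at each threshold, and tests score-trait
#' association under relatedness adjustment for the same trait, for the
#' cross trait, and for the sensitivity re-run excluding affected
#' (cross-trait case) individuals.
#'
#' @param config a [study_config()] whose simulation block includes a
#'   `gwas` truth (or whose paths name `summary_stats` and `genotypes`).
#' @export
run_prs <- function(config) {
  set.seed(config$seed)
  dat <- load_study_data(config)
  if (!is.null(config$simulation)) {
    gwas <- config$simulation$gwas %||% gwas_truth(seed = config$seed)
    sumstats_df <- simulate_training_gwas(gwas, seed = config$seed + 2e6)
    tmp <- tempfile(fileext = ".tsv")
    utils::write.table(sumstats_df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stats <- read_summary_stats(tmp)
    unlink(tmp)
    geno <- simulate_target_genotypes(dat$ped, gwas,
                                      seed = config$seed + 3e6)
    # target trait carrying the scored panel at a sub-1% variance share:
    # the weak-prediction regime typical of cross-cohort polygenic
    # scores for pain; the family phenotype is kept for the cross-trait
    # null
    share <- config$simulation$target_snp_share %||% 0.008
    snp_trait <- simulate_snp_trait(geno, gwas, h2 = share,
                                    seed = config$seed + 4e6)
    dat$phenotypes$cpg_snp <- as.numeric(snp_trait[dat$phenotypes$id])
    same_trait <- "cpg_snp"
  } else {
    stats <- read_summary_stats(config$paths$summary_stats)
    fmt <- if (grepl("\\.vcf$", config$paths$genotypes)) "vcf"
           else "dosage_tsv"
    geno <- read_genotypes(config$paths$genotypes, fmt)
    same_trait <- "cpg"
  }
  profile <- threshold_and_score(stats, geno,
                                 thresholds = config$thresholds)
  A <- dat$structures$additive
  assoc_same <- prs_mixed_association(profile, dat$phenotypes, same_trait,
                                      structure = A)
  assoc_cross <- prs_mixed_association(profile, dat$phenotypes, "mdd",
                                       structure = A)
  unaffected <- dat$phenotypes[dat$phenotypes$mdd == 0, , drop = FALSE]
  assoc_excl <- prs_mixed_association(profile, unaffected, same_trait,
                                      structure = A)
  assoc_same$analysis <- "same_trait"
  assoc_cross$analysis <- "cross_trait"
  assoc_excl$analysis <- "same_trait_excluding_affected"
  tab <- rbind(assoc_same, assoc_cross, assoc_excl)
  write_report(paste0("# n target = ", nrow(dat$phenotypes),
                      "; n excluding affected = ", nrow(unaffected)),
               tab, config, "prs")
  list(profile = profile, associations = tab,
       n_target = nrow(dat$phenotypes), n_excluding = nrow(unaffected),
       data = dat)
}
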