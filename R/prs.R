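#' Read GWAS summary statistics for polygenic scoring
#'
#' @param path TSV with a header.
#' @param col_map named character vector mapping the required fields
#'   (`snp`, `effect_allele`, `other_allele`, `weight`, `p_value`) to the
#'   file's column names.
#' @return A `summary_stats` data.frame with standardized column names.
#' @export
read_summary_stats <- function(path,
                               col_map = c(snp = "SNP",
                                           effect_allele = "A1",
                                           other_allele = "A2",
                                           weight = "BETA",
                                           p_value = "P")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(col_map), names(df))
  if (length(missing_cols))
    stop("summary-statistics file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(snp = as.character(df[[col_map["snp"]]]),
                    effect_allele = toupper(df[[col_map["effect_allele"]]]),
                    other_allele = toupper(df[[col_map["other_allele"]]]),
                    weight = as.numeric(df[[col_map["weight"]]]),
                    p_value = as.numeric(df[[col_map["p_value"]]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp))
    stop("duplicated SNP id(s): ",
         paste(unique(out$snp[duplicated(out$snp)]), collapse = ", "))
  bad_al <- !(out$effect_allele %in% c("A", "C", "G", "T")) |
    !(out$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad_al))
    stop("non-ACGT allele(s) for SNP(s): ",
         paste(out$snp[bad_al], collapse = ", "))
  if (any(is.na(out$p_value) | out$p_value <= 0 | out$p_value > 1))
    stop("p-values must lie in (0, 1]; offending SNP(s): ",
         paste(out$snp[is.na(out$p_value) | out$p_value <= 0 |
                         out$p_value > 1], collapse = ", "))
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Read target genotypes from VCF (GT fields) or a dosage TSV
#'
#' For VCF input the dosage counts the ALT allele; `./.` becomes a
#' missing dosage. The dosage TSV is the format written by
#' [write_dosage_tsv()].
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "vcf") read_vcf_gt(path) else read_dosage_tsv(path)
}

read_vcf_gt <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: no #CHROM header line")
  header <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10) stop("VCF has no sample columns")
  ids <- header[-(1:9)]
  body <- lines[seq.int(hdr[1] + 1, length(lines))]
  body <- body[nzchar(body)]
  snp_id <- character(length(body)); ref <- alt <- character(length(body))
  dos <- matrix(NA_real_, length(ids), length(body))
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop("malformed VCF line ", hdr[1] + k, ": expected ",
           length(header), " fields, found ", length(f))
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_pos <- match("GT", fmt)
    if (is.na(gt_pos))
      stop("malformed VCF line ", hdr[1] + k, ": no GT in FORMAT")
    snp_id[k] <- f[3]; ref[k] <- f[4]; alt[k] <- f[5]
    gt <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE),
                 `[`, character(1), gt_pos)
    alleles <- strsplit(gt, "[/|]")
    dos[, k] <- vapply(alleles, function(a) {
      if (any(a == ".") || length(a) != 2) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  dimnames(dos) <- list(ids, snp_id)
  structure(list(ids = ids,
                 snps = data.frame(snp_id = snp_id, counted_allele = alt,
                                   other_allele = ref,
                                   stringsAsFactors = FALSE),
                 dosages = dos),
            class = "genotype_matrix")
}

read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  al_rows <- df$id %in% c("counted_allele", "other_allele")
  counted <- unlist(df[df$id == "counted_allele", -1])
  other <- unlist(df[df$id == "other_allele", -1])
  dat <- df[!al_rows, , drop = FALSE]
  dos <- as.matrix(dat[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- dat$id
  structure(list(ids = dat$id,
                 snps = data.frame(snp_id = colnames(dos),
                                   counted_allele = unname(counted),
                                   other_allele = unname(other),
                                   stringsAsFactors = FALSE),
                 dosages = dos),
            class = "genotype_matrix")
}

flip_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

#' Align summary-statistic weights to target genotype alleles
#'
#' PRSice-style matching on the overlapping SNPs: when the counted
#' allele equals the effect allele the weight is kept; when the alleles
#' are swapped the weight's sign is flipped; strand-ambiguous SNPs
#' (A/T, C/G) are excluded by default, as are allele pairs that match
#' neither orientation (including after strand flip when
#' `allow_strand_flip`). Every exclusion is reported with its reason.
#'
#' @param stats a `summary_stats`.
#' @param geno a `genotype_matrix`.
#' @param exclude_ambiguous drop A/T and C/G SNPs.
#' @param allow_strand_flip also try the reverse-complement orientation.
#' @return list with `weights` (named, aligned to the counted allele),
#'   `p_values` (named), and `exclusions` (data.frame `snp`, `reason`).
#' @export
align_alleles <- function(stats, geno, exclude_ambiguous = TRUE,
                          allow_strand_flip = TRUE) {
  common <- intersect(stats$snp, geno$snps$snp_id)
  if (!length(common))
    stop("no overlapping SNPs between summary statistics and genotypes")
  st <- stats[match(common, stats$snp), ]
  gn <- geno$snps[match(common, geno$snps$snp_id), ]
  excl <- data.frame(snp = character(0), reason = character(0))
  drop_snp <- function(sn, reason)
    excl <<- rbind(excl, data.frame(snp = sn, reason = reason))

  ambiguous <- (st$effect_allele == flip_allele(st$other_allele))
  w <- rep(NA_real_, length(common))
  same <- st$effect_allele == gn$counted_allele &
    st$other_allele == gn$other_allele
  swapped <- st$effect_allele == gn$other_allele &
    st$other_allele == gn$counted_allele
  fe <- flip_allele(st$effect_allele); fo <- flip_allele(st$other_allele)
  s_same <- fe == gn$counted_allele & fo == gn$other_allele
  s_swap <- fe == gn$other_allele & fo == gn$counted_allele

  for (k in seq_along(common)) {
    if (exclude_ambiguous && ambiguous[k]) {
      drop_snp(common[k], "strand-ambiguous")
    } else if (same[k]) {
      w[k] <- st$weight[k]
    } else if (swapped[k]) {
      w[k] <- -st$weight[k]
    } else if (allow_strand_flip && s_same[k]) {
      w[k] <- st$weight[k]
    } else if (allow_strand_flip && s_swap[k]) {
      w[k] <- -st$weight[k]
    } else {
      drop_snp(common[k], "allele mismatch")
    }
  }
  keep <- !is.na(w)
  list(weights = stats::setNames(w[keep], common[keep]),
       p_values = stats::setNames(st$p_value[keep], common[keep]),
       exclusions = excl)
}

#' Polygenic risk scores at p-value thresholds
#'
#' For each threshold pT the score of an individual is the dosage-
#' weighted sum over SNPs with discovery p-value at or below pT, after
#' allele alignment. Missing dosages are imputed with twice the counted-
#' allele sample frequency. Raw and standardized (mean 0, SD 1) scores
#' are returned with the SNP count per threshold.
#'
#' @param stats a `summary_stats`.
#' @param geno a `genotype_matrix`.
#' @param thresholds numeric vector of p-value cutoffs.
#' @param ... passed to [align_alleles()].
#' @return A `prs_profile`: list with `scores` (data.frame `id`, then one
#'   raw and one standardized column per threshold), `n_snps_used`,
#'   `thresholds`, and the alignment `exclusions`.
#' @export
threshold_and_score <- function(stats, geno,
                                thresholds = c(0.01, 0.05, 0.1, 0.5),
                                ...) {
  al <- align_alleles(stats, geno, ...)
  dos <- geno$dosages[, names(al$weights), drop = FALSE]
  # SNPs with no observed dosage at all are dropped, not imputed
  all_missing <- colSums(!is.na(dos)) == 0
  if (any(all_missing)) {
    al$exclusions <- rbind(al$exclusions,
                           data.frame(snp = colnames(dos)[all_missing],
                                      reason = "all dosages missing"))
    dos <- dos[, !all_missing, drop = FALSE]
    al$weights <- al$weights[!all_missing]
    al$p_values <- al$p_values[!all_missing]
  }
  freq <- colMeans(dos, na.rm = TRUE) / 2
  for (j in seq_len(ncol(dos))) {
    nas <- is.na(dos[, j])
    if (any(nas)) dos[nas, j] <- 2 * freq[j]
  }
  thresholds <- sort(thresholds)
  scores <- data.frame(id = geno$ids, stringsAsFactors = FALSE)
  n_used <- stats::setNames(integer(length(thresholds)),
                            paste0("pT_", thresholds))
  for (t in seq_along(thresholds)) {
    sel <- al$p_values <= thresholds[t]
    n_used[t] <- sum(sel)
    nm <- paste0("pT_", thresholds[t])
    if (!any(sel)) {
      warning("threshold ", thresholds[t], " retains 0 SNPs; profile absent")
      next
    }
    raw <- drop(dos[, sel, drop = FALSE] %*% al$weights[sel])
    scores[[nm]] <- raw
    sdr <- stats::sd(raw)
    scores[[paste0(nm, "_std")]] <-
      if (sdr > 0) (raw - mean(raw)) / sdr else raw * 0
  }
  structure(list(scores = scores, n_snps_used = n_used,
                 thresholds = thresholds, exclusions = al$exclusions),
            class = "prs_profile")
}

#' @exportS3Method base::print
print.prs_profile <- function(x, ...) {
  cat("<prs_profile> ", nrow(x$scores), " individuals; SNPs per threshold: ",
      paste(names(x$n_snps_used), x$n_snps_used, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Leading axes of genotypic ancestry variation
#'
#' Top-k eigenvectors of the covariance of centred, frequency-
#' standardized dosages (the usual PCA adjustment for population
#' structure, filling the role of multidimensional-scaling components).
#' Sign convention: the largest-magnitude loading of each axis is
#' positive.
#'
#' @param geno a `genotype_matrix`.
#' @param k number of components.
#' @return matrix (individuals x k) of component scores.
#' @export
ancestry_components <- function(geno, k = 4) {
  if (k == 0) return(matrix(numeric(0), length(geno$ids), 0,
                            dimnames = list(geno$ids, NULL)))
  dos <- geno$dosages
  freq <- colMeans(dos, na.rm = TRUE) / 2
  keep <- freq > 0 & freq < 1
  if (sum(keep) < k) stop("k = ", k, " exceeds the number of variable SNPs")
  dos <- dos[, keep, drop = FALSE]; freq <- freq[keep]
  Z <- sweep(dos, 2, 2 * freq)
  Z <- sweep(Z, 2, sqrt(2 * freq * (1 - freq)), "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = k, nv = 0)
  if (sv$d[k] < 1e-12) stop("k = ", k, " exceeds the genotypic rank")
  pcs <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    if (pcs[which.max(abs(pcs[, j])), j] < 0) pcs[, j] <- -pcs[, j]
  }
  dimnames(pcs) <- list(geno$ids, paste0("PC", seq_len(k)))
  pcs
}

#' Relatedness-aware association of a polygenic score with a trait
#'
#' The standardized score enters as a fixed effect in a mixed model with
#' the additive relationship structure as a random effect (plus sex,
#' age, age squared and optional ancestry components). Under the REML
#' backend the coefficient, Wald 95% interval and p-value are reported;
#' under the Gibbs backend the posterior mean, mode, credible interval
#' and tail probability. Ordinal phenotypes are standardized so the
#' coefficient is per-SD. Setting `structure = NULL` gives the
#' unrelated-cohort analysis (plain fixed-effects model).
#'
#' @param profile a `prs_profile` (all thresholds are tested) or a named
#'   numeric vector of scores.
#' @param phenotypes data.frame with `id`, the response and covariates.
#' @param response phenotype column name.
#' @param structure additive `relationship_structure`, or `NULL`.
#' @param fixed_effects covariate names as in [mixed_model_spec()].
#' @param ancestry optional matrix of ancestry components (rownames ids).
#' @param backend `"reml"` or `"gibbs"`.
#' @param standardize_response divide the response by its SD.
#' @param mcmc_control Gibbs run lengths, see [mcmc_profile()].
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_snps`, `beta`, `lower`, `upper`, `p_value`, `variance_explained`.
#' @export
prs_mixed_association <- function(profile, phenotypes, response,
                                  structure = NULL,
                                  fixed_effects = c("sex", "age", "age2"),
                                  ancestry = NULL,
                                  backend = c("reml", "gibbs"),
                                  standardize_response = TRUE,
                                  mcmc_control = mcmc_profile("fast")) {
  backend <- match.arg(backend)
  if (is.numeric(profile)) {
    if (!is.finite(stats::sd(profile)) || stats::sd(profile) == 0)
      stop("constant polygenic score")
    profile <- list(scores = data.frame(id = names(profile),
                                        pT_all = profile,
                                        pT_all_std = as.numeric(
                                          scale(profile))),
                    thresholds = NA_real_,
                    n_snps_used = c(pT_all = NA_integer_))
    class(profile) <- "prs_profile"
  }
  dat <- phenotypes
  y <- as.numeric(dat[[response]])
  if (standardize_response) {
    if (stats::sd(y, na.rm = TRUE) == 0) stop("constant phenotype")
    y <- y / stats::sd(y, na.rm = TRUE)
    dat[[response]] <- y
  }
  if (!is.null(ancestry)) {
    anc <- ancestry[match(dat$id, rownames(ancestry)), , drop = FALSE]
    for (j in seq_len(ncol(anc))) dat[[colnames(anc)[j]]] <- anc[, j]
  }
  th_names <- grep("_std$", names(profile$scores), value = TRUE)
  out <- NULL
  for (nm in th_names) {
    thr_label <- sub("_std$", "", nm)
    sc <- profile$scores[[nm]][match(dat$id, profile$scores$id)]
    sdv <- stats::sd(sc, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0)
      stop("constant polygenic score at ", thr_label)
    dat$prs <- sc
    fx <- c(fixed_effects,
            if (!is.null(ancestry)) colnames(ancestry), "prs")
    if (backend == "reml") {
      if (is.null(structure)) {
        fml <- stats::reformulate(ifelse(fx == "age2", "I(age^2)", fx),
                                  response = response)
        lmfit <- stats::lm(fml, data = dat)
        cf <- summary(lmfit)$coefficients
        b <- cf["prs", 1]; se <- cf["prs", 2]; p <- cf["prs", 4]
      } else {
        sp <- mixed_model_spec(response, "gaussian", fixed_effects = fx,
                               random_components = "additive")
        fit <- fit_reml(sp, dat, list(additive = structure))
        row <- fit$fixed_effects[fit$fixed_effects$term == "prs", ]
        b <- row$estimate; se <- row$se
        p <- 2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
      }
      lo <- b - 1.96 * se; hi <- b + 1.96 * se
    } else {
      sp <- mixed_model_spec(response,
                             if (length(unique(y[!is.na(y)])) == 2)
                               "binary" else "ordinal",
                             fixed_effects = fx,
                             random_components = "additive",
                             mcmc_control = mcmc_control)
      fit <- fit_gibbs_ordinal(sp, dat, list(additive = structure))
      draws <- fit$fixed_samples[, "prs"]
      b <- mean(draws)
      lo <- stats::quantile(draws, 0.025, names = FALSE)
      hi <- stats::quantile(draws, 0.975, names = FALSE)
      p <- 2 * min(mean(draws > 0), mean(draws < 0))
      p <- max(p, 1 / length(draws))
    }
    r2 <- prs_variance_explained(b, dat$prs, y[match(dat$id, dat$id)])
    out <- rbind(out, data.frame(threshold = thr_label,
                                 n_snps = unname(
                                   profile$n_snps_used[thr_label]),
                                 beta = b, lower = lo, upper = hi,
                                 p_value = p, variance_explained = r2))
  }
  rownames(out) <- NULL
  out
}

#' Variance in a phenotype explained by a fitted polygenic score
#'
#' The score is multiplied by its regression coefficient; the variance of
#' that product divided by the phenotypic variance gives a coefficient of
#' determination between 0 and 1: `R2 = beta^2 Var(score) / Var(y)`.
#'
#' @param beta fitted coefficient of the score.
#' @param score the score values the coefficient was fitted on.
#' @param phenotype observed phenotype vector.
#' @export
prs_variance_explained <- function(beta, score, phenotype) {
  vp <- stats::var(phenotype, na.rm = TRUE)
  if (is.na(vp) || vp == 0) stop("zero phenotype variance")
  ok <- stats::complete.cases(score, phenotype)
  beta^2 * stats::var(score[ok]) / stats::var(phenotype[ok])
}
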