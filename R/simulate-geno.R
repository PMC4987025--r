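#' Ground truth of a simulated discovery ("training") GWAS
#'
#' Fixes, once and deterministically from its seed, the SNP panel
#' (identifiers, effect/other alleles, minor-allele frequencies) and the
#' true per-allele effects of the causal subset, scaled so the causal
#' SNPs jointly explain `h2_snp` of the scored trait's variance under
#' Hardy-Weinberg allele frequencies.
#'
#' @param n_snps,n_causal SNP counts (`n_causal <= n_snps`).
#' @param h2_snp SNP heritability of the scoring trait in \[0, 1\].
#' @param maf_range interval of minor-allele frequencies in (0, 0.5\].
#' @param n_train training sample size.
#' @param seed integer seed fixing panel and effects.
#' @param ambiguous_fraction fraction of SNPs given strand-ambiguous
#'   (A/T or C/G) allele pairs, to exercise the scoring exclusions.
#' @export
gwas_truth <- function(n_snps = 2000, n_causal = 200, h2_snp = 0.3,
                       maf_range = c(0.05, 0.5), n_train = 20000,
                       seed = 1, ambiguous_fraction = 0) {
  stopifnot(n_causal <= n_snps, h2_snp >= 0, h2_snp <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  rng <- local({ set.seed(seed)
    maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    pairs_ok <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
    pairs_amb <- rbind(c("A", "T"), c("C", "G"))
    amb <- stats::runif(n_snps) < ambiguous_fraction
    pick <- function(p) p[sample(nrow(p), 1), ]
    al <- t(vapply(amb, function(a)
      pick(if (a) pairs_amb else pairs_ok), character(2)))
    beta <- numeric(n_snps)
    causal <- sample(n_snps, n_causal)
    beta[causal] <- stats::rnorm(n_causal)
    vg <- sum(2 * maf * (1 - maf) * beta^2)
    if (vg > 0 && h2_snp > 0) beta <- beta * sqrt(h2_snp / vg)
    else beta[] <- 0
    list(maf = maf, al = al, beta = beta)
  })
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(n_snps)),
                     effect_allele = rng$al[, 1],
                     other_allele = rng$al[, 2],
                     maf = rng$maf, beta = rng$beta,
                     stringsAsFactors = FALSE)
  structure(list(n_snps = n_snps, n_causal = n_causal, h2_snp = h2_snp,
                 maf_range = maf_range, n_train = n_train, seed = seed,
                 snps = snps),
            class = "gwas_truth")
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders are drawn at Hardy-Weinberg equilibrium from each SNP's
#' allele frequency; non-founders receive one Mendelian allele from each
#' parent (an unknown parent transmits a population allele). Dosages
#' count the effect allele.
#'
#' @param ped a [pedigree].
#' @param gwas a [gwas_truth()].
#' @param seed optional integer seed.
#' @param missing_rate per-entry probability of a missing genotype.
#' @return A `genotype_matrix`: list with `ids`, `snps` (data.frame with
#'   `snp_id`, `counted_allele`, `other_allele`) and `dosages`
#'   (individuals x SNPs, values 0/1/2 or `NA`).
#' @export
simulate_target_genotypes <- function(ped, gwas, seed = NULL,
                                      missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  ord <- topological_order(ped)
  n <- length(ord); m <- gwas$n_snps
  pos <- seq_len(n); names(pos) <- ord
  fi <- ifelse(is.na(ped$father), 0L, pos[ped$father])[match(ord, ped$id)]
  mi <- ifelse(is.na(ped$mother), 0L, pos[ped$mother])[match(ord, ped$id)]
  maf <- gwas$snps$maf
  # paternal and maternal allele indicators, row per individual
  pat <- matrix(0L, n, m); mat <- matrix(0L, n, m)
  transmit <- function(pidx) {
    if (pidx == 0L) return(stats::rbinom(m, 1L, maf))
    het_pick <- stats::rbinom(m, 1L, 0.5)
    ifelse(pat[pidx, ] + mat[pidx, ] == 2L, 1L,
           ifelse(pat[pidx, ] + mat[pidx, ] == 0L, 0L,
                  ifelse(het_pick == 1L, pat[pidx, ], mat[pidx, ])))
  }
  for (i in seq_len(n)) {
    if (fi[i] == 0L && mi[i] == 0L) {
      pat[i, ] <- stats::rbinom(m, 1L, maf)
      mat[i, ] <- stats::rbinom(m, 1L, maf)
    } else {
      pat[i, ] <- transmit(fi[i])
      mat[i, ] <- transmit(mi[i])
    }
  }
  dos <- pat + mat
  if (missing_rate > 0)
    dos[matrix(stats::runif(n * m) < missing_rate, n, m)] <- NA_integer_
  rownames(dos) <- ord
  dos <- dos[ped$id, , drop = FALSE]
  colnames(dos) <- gwas$snps$snp_id
  structure(list(ids = ped$id,
                 snps = data.frame(snp_id = gwas$snps$snp_id,
                                   counted_allele = gwas$snps$effect_allele,
                                   other_allele = gwas$snps$other_allele,
                                   stringsAsFactors = FALSE),
                 dosages = dos),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$ids), " individuals x ",
      nrow(x$snps), " SNPs, ", sum(is.na(x$dosages)), " missing\n",
      sep = "")
  invisible(x)
}

#' Simulate an independent training GWAS and its summary statistics
#'
#' An unrelated sample of `n_train` individuals is drawn at
#' Hardy-Weinberg equilibrium (distinct from any target pedigree); the
#' scored trait is the causal-SNP genetic value plus normal noise scaled
#' to the truth's SNP heritability. Each SNP is tested by marginal linear
#' regression of the trait on dosage.
#'
#' @param gwas a [gwas_truth()].
#' @param seed optional integer seed.
#' @param chunk SNPs processed per block (memory control).
#' @return data.frame with columns `SNP`, `A1` (effect allele), `A2`,
#'   `BETA`, `SE`, `P`.
#' @export
simulate_training_gwas <- function(gwas, seed = NULL, chunk = 500) {
  if (!is.null(seed)) set.seed(seed)
  n <- gwas$n_train; m <- gwas$n_snps
  maf <- gwas$snps$maf; beta <- gwas$snps$beta
  # pass 1: genetic values (chunked to bound memory); the chunked draws
  # are reproduced in pass 2 from a stored per-chunk seed
  starts <- seq(1, m, by = chunk)
  chunk_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(starts) + 1L)
  g <- numeric(n)
  for (ci in seq_along(starts)) {
    cols <- starts[ci]:min(starts[ci] + chunk - 1, m)
    set.seed(chunk_seeds[ci])
    G <- matrix(stats::rbinom(n * length(cols), 2L,
                              rep(maf[cols], each = n)), n)
    g <- g + drop(G %*% beta[cols])
  }
  vres <- max(1 - gwas$h2_snp, 1e-8)
  set.seed(chunk_seeds[length(chunk_seeds)])
  y <- g + stats::rnorm(n, 0, sqrt(vres))
  est <- se <- pv <- numeric(m)
  for (ci in seq_along(starts)) {
    cols <- starts[ci]:min(starts[ci] + chunk - 1, m)
    set.seed(chunk_seeds[ci])
    G <- matrix(stats::rbinom(n * length(cols), 2L,
                              rep(maf[cols], each = n)), n)
    Gc <- sweep(G, 2, colMeans(G))
    sxx <- colSums(Gc^2)
    sxy <- drop(crossprod(Gc, y - mean(y)))
    b <- sxy / sxx
    rss <- pmax(sum((y - mean(y))^2) - b^2 * sxx, 1e-12) # per SNP
    s <- sqrt(rss / (n - 2) / sxx)
    est[cols] <- b; se[cols] <- s
    pv[cols] <- 2 * stats::pt(abs(b / s), df = n - 2, lower.tail = FALSE)
  }
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  data.frame(SNP = gwas$snps$snp_id, A1 = gwas$snps$effect_allele,
             A2 = gwas$snps$other_allele, BETA = est, SE = se, P = pv,
             stringsAsFactors = FALSE)
}

#' Simulate a target trait driven by the scored SNPs
#'
#' Genetic value from the panel's true effects on the target genotypes,
#' plus independent normal noise so the SNP set explains `h2` of the
#' trait variance. Used to validate polygenic-score power end to end.
#'
#' @param geno a `genotype_matrix` (dosages of the panel's effect alleles).
#' @param gwas the matching [gwas_truth()].
#' @param h2 variance share explained by the panel (defaults to the
#'   truth's `h2_snp`).
#' @param seed optional integer seed.
#' @return numeric phenotype vector named by individual id.
#' @export
simulate_snp_trait <- function(geno, gwas, h2 = gwas$h2_snp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dos <- geno$dosages
  dos[is.na(dos)] <- 0
  g <- drop(dos %*% gwas$snps$beta)
  vg <- stats::var(g)
  if (vg > 0 && h2 > 0) {
    g <- g * sqrt(h2 / vg)
    y <- g + stats::rnorm(length(g), 0, sqrt(1 - h2))
  } else {
    y <- stats::rnorm(nrow(dos))
  }
  stats::setNames(y, geno$ids)
}

#' Write genotypes as a minimal VCF 4.2 (GT only)
#'
#' REF is the other allele and ALT the counted (effect) allele, so GT
#' counts of the ALT allele equal the stored dosage; missing dosages
#' become `./.`.
#'
#' @param geno a `genotype_matrix`.
#' @param path output file.
#' @export
write_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=famvc",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", geno$ids),
                     collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  m <- nrow(geno$snps)
  dos <- geno$dosages
  for (j in seq_len(m)) {
    gt <- ifelse(is.na(dos[, j]), "./.", gt_codes[dos[, j] + 1L])
    writeLines(paste(c("1", j, geno$snps$snp_id[j],
                       geno$snps$other_allele[j],
                       geno$snps$counted_allele[j],
                       ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotypes as a dosage TSV (SNP columns, id rows)
#' @param geno a `genotype_matrix`.
#' @param path output file.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(id = geno$ids, geno$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  al <- data.frame(id = c("counted_allele", "other_allele"),
                   rbind(geno$snps$counted_allele, geno$snps$other_allele),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(al) <- names(df)
  utils::write.table(rbind(al, df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
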