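#' Write / read a relationship structure as coordinate-format text
#'
#' Triplets `i  j  value` (1-based, upper triangle including diagonal)
#' with a `# id:` sidecar header carrying the ordered individual ids and
#' the structure kind.
#'
#' @param S a `relationship_structure`.
#' @param path output file.
#' @export
write_relationship <- function(S, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# kind: ", S$kind),
               paste0("# ids: ", paste(S$ids, collapse = "\t"))), con)
  Tm <- methods::as(methods::as(S$matrix, "generalMatrix"),
                    "TsparseMatrix")
  keep <- Tm@i <= Tm@j
  df <- data.frame(i = Tm@i[keep] + 1L, j = Tm@j[keep] + 1L,
                   x = Tm@x[keep])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship
#' @param path file written by [write_relationship()].
#' @export
read_relationship <- function(path) {
  hdr <- readLines(path, n = 2)
  kind <- sub("^# kind: ", "", hdr[1])
  ids <- strsplit(sub("^# ids: ", "", hdr[2]), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, skip = 2,
                          col.names = c("i", "j", "x"))
  n <- length(ids)
  m <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$x,
                            dims = c(n, n), symmetric = TRUE)
  out <- relationship_structure(ids, m, kind)
  if (kind != "additive") { # recover the partition for the Gibbs backend
    bl <- covariance_blocks(list(methods::as(out$matrix, "CsparseMatrix")),
                            n)
    attr(out, "groups") <- lapply(bl[lengths(bl) > 1],
                                  function(ix) ids[ix])
  }
  out
}

#' Write the cohort files of a simulated study
#'
#' Pedigree, couples, households, and phenotypes as TSV; the truth
#' manifest as YAML.
#'
#' @param ped a [pedigree].
#' @param phenotypes phenotype data.frame from [simulate_phenotypes()].
#' @param truth the [simulation_truth()] used.
#' @param dir output directory (created if needed).
#' @return invisible named vector of written paths.
#' @export
write_cohort <- function(ped, phenotypes, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  ped_df <- data.frame(id = ped$id,
                       father = ifelse(is.na(ped$father), "0", ped$father),
                       mother = ifelse(is.na(ped$mother), "0", ped$mother),
                       sex = ped$sex)
  utils::write.table(ped_df, p("pedigree.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(ped$couples), p("couples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hh <- if (length(ped$households))
    data.frame(household = rep(names(ped$households),
                               lengths(ped$households)),
               id = unlist(ped$households, use.names = FALSE))
  else data.frame(household = character(0), id = character(0))
  utils::write.table(hh, p("households.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(phenotypes, p("phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- unclass(truth)
  tr$grade_freq <- as.list(tr$grade_freq)
  yaml::write_yaml(tr, p("truth.yaml"))
  invisible(c(pedigree = p("pedigree.tsv"), couples = p("couples.tsv"),
              households = p("households.tsv"),
              phenotypes = p("phenotypes.tsv"), truth = p("truth.yaml")))
}
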