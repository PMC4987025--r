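#' Construct a pedigree object
#'
#' A `pedigree` holds individuals with parent links plus the group
#' assignments (couples, households) from which shared-environment
#' covariance structures are built. Sibships are derived from shared
#' parent pairs.
#'
#' @param id character vector of unique individual ids.
#' @param father,mother character vectors of parent ids; `NA`, `""` or
#'   `"0"` denote an unknown parent.
#' @param sex character vector: `"female"`, `"male"` or `"unknown"`
#'   (abbreviations `"f"`/`"F"`/`"1"` and `"m"`/`"M"`/`"2"` are accepted).
#' @param couples two-column matrix or data.frame of id pairs, or `NULL`
#'   to infer couples as parent pairs sharing at least one offspring.
#' @param households data.frame with columns `household` and `id`, or
#'   `NULL` for no household structure.
#' @return An object of class `pedigree` with elements `id`, `father`,
#'   `mother`, `sex` (all aligned vectors; missing parent is `NA`),
#'   `couples` (two-column character matrix), `households` (named list of
#'   id vectors) and `sibships` (named list of id vectors keyed by
#'   `"father|mother"`).
#' @examples
#' ped <- pedigree(id = c("F", "M", "C"),
#'                 father = c(NA, NA, "F"),
#'                 mother = c(NA, NA, "M"),
#'                 sex = c("male", "female", "female"))
#' ped$sibships
#' @export
pedigree <- function(id, father = NULL, mother = NULL, sex = NULL,
                     couples = NULL, households = NULL) {
  id <- as.character(id)
  n <- length(id)
  norm_parent <- function(p) {
    if (is.null(p)) return(rep(NA_character_, n))
    p <- as.character(p)
    p[p %in% c("", "0", "NA") | is.na(p)] <- NA_character_
    p
  }
  father <- norm_parent(father)
  mother <- norm_parent(mother)
  sex <- normalize_sex(sex, n)

  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  for (p in list(father, mother)) {
    bad <- !is.na(p) & !(p %in% id)
    if (any(bad))
      stop("unknown parent id(s): ", paste(unique(p[bad]), collapse = ", "))
  }

  check_acyclic(id, father, mother)

  sib_key <- ifelse(is.na(father) & is.na(mother), NA_character_,
                    paste(ifelse(is.na(father), "*", father),
                          ifelse(is.na(mother), "*", mother), sep = "|"))
  sibships <- split(id[!is.na(sib_key)], sib_key[!is.na(sib_key)])

  if (is.null(couples)) {
    both <- !is.na(father) & !is.na(mother)
    couples <- unique(cbind(father[both], mother[both]))
  } else {
    couples <- as.matrix(couples)[, 1:2, drop = FALSE]
    storage.mode(couples) <- "character"
    if (any(couples[, 1] == couples[, 2]))
      stop("a couple must consist of two distinct ids")
    bad <- !(c(couples) %in% id)
    if (any(bad))
      stop("couple member(s) not in pedigree: ",
           paste(unique(c(couples)[bad]), collapse = ", "))
    couples <- unique(t(apply(couples, 1, sort)))
    if (nrow(couples) == 0) couples <- matrix(character(), ncol = 2)
  }
  colnames(couples) <- c("id1", "id2")

  if (is.null(households)) {
    households <- list()
  } else {
    hh <- as.data.frame(households)
    names(hh)[1:2] <- c("household", "id")
    hh$id <- as.character(hh$id)
    bad <- !(hh$id %in% id)
    if (any(bad))
      stop("household member(s) not in pedigree: ",
           paste(unique(hh$id[bad]), collapse = ", "))
    if (anyDuplicated(hh$id))
      stop("individual(s) assigned to more than one household: ",
           paste(unique(hh$id[duplicated(hh$id)]), collapse = ", "))
    households <- split(hh$id, as.character(hh$household))
  }

  structure(list(id = id, father = father, mother = mother, sex = sex,
                 couples = couples, households = households,
                 sibships = sibships),
            class = "pedigree")
}

normalize_sex <- function(sex, n) {
  if (is.null(sex)) return(rep("unknown", n))
  s <- tolower(as.character(sex))
  out <- rep("unknown", n)
  out[s %in% c("f", "female", "1")] <- "female"
  out[s %in% c("m", "male", "2")] <- "male"
  out
}

check_acyclic <- function(id, father, mother) {
  idx <- seq_along(id)
  names(idx) <- id
  fi <- ifelse(is.na(father), 0L, idx[father])
  mi <- ifelse(is.na(mother), 0L, idx[mother])
  state <- integer(length(id)) # 0 unvisited, 1 on stack, 2 done
  for (start in idx) {
    if (state[start] != 0L) next
    stack <- start; path <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      if (state[v] == 0L) {
        state[v] <- 1L
        path <- c(path, v)
        for (p in c(fi[v], mi[v])) {
          if (p > 0L) {
            if (state[p] == 1L) {
              cyc <- path[which(path == p)[1]:length(path)]
              stop("cycle in parent graph: ",
                   paste(id[cyc], collapse = " -> "), " -> ", id[p])
            }
            if (state[p] == 0L) stack <- c(stack, p)
          }
        }
      } else {
        stack <- stack[-length(stack)]
        if (state[v] == 1L) {
          state[v] <- 2L
          path <- path[-length(path)]
        }
      }
    }
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", length(x$id), " individuals, ",
      sum(!is.na(x$father) | !is.na(x$mother)), " non-founders, ",
      nrow(x$couples), " couples, ", length(x$sibships), " sibships, ",
      length(x$households), " households\n", sep = "")
  invisible(x)
}

#' Read a pedigree (and optional couple/household assignments) from TSV
#'
#' The pedigree file must have columns `id`, `father`, `mother`, `sex`
#' (tab-separated, with header); `"0"` or an empty field marks an unknown
#' parent. The couples file has columns `id1`, `id2`; the households file
#' has columns `household`, `id`. When `couples_file` is absent, couples
#' are inferred as parent pairs with at least one common offspring.
#'
#' @param pedigree_file path to the pedigree TSV.
#' @param couples_file,households_file optional paths.
#' @return A [pedigree] object.
#' @export
parse_pedigree <- function(pedigree_file, couples_file = NULL,
                           households_file = NULL) {
  ped <- utils::read.delim(pedigree_file, colClasses = "character")
  need <- c("id", "father", "mother")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns id, father, mother (and sex)")
  couples <- if (!is.null(couples_file))
    utils::read.delim(couples_file, colClasses = "character")
  households <- if (!is.null(households_file))
    utils::read.delim(households_file, colClasses = "character")
  pedigree(ped$id, ped$father, ped$mother, ped$sex,
           couples = couples, households = households)
}

#' Order pedigree members so that parents precede offspring
#'
#' Kahn topological sort of the parent graph; ties are broken by input
#' order, so the result is deterministic.
#'
#' @param ped a [pedigree].
#' @return character vector of ids.
#' @export
topological_order <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  idx <- seq_len(n); names(idx) <- ped$id
  fi <- ifelse(is.na(ped$father), 0L, idx[ped$father])
  mi <- ifelse(is.na(ped$mother), 0L, idx[ped$mother])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(c(fi[i], mi[i]))) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  out <- integer(0)
  avail <- which(indeg == 0L) # already in input order
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- sort(c(avail, ch))
    }
  }
  if (length(out) != n) stop("cycle in parent graph")
  ped$id[out]
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Builds A by the tabular method in topological order: for individual i
#' with parents f and m, `A[i,i] = 1 + 0.5 * A[f,m]` and
#' `A[i,j] = 0.5 * (A[j,f] + A[j,m])` for previously placed j, a missing
#' parent contributing 0. Entries are expected additive-genetic
#' covariances relative to the founder population (twice the kinship
#' coefficient); the diagonal is 1 + the inbreeding coefficient.
#'
#' @param ped a [pedigree].
#' @return A `relationship_structure`: list with `ids` (topological
#'   order), `matrix` (sparse symmetric [Matrix::dsCMatrix-class]) and
#'   `kind = "additive"`.
#' @examples
#' trio <- pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"))
#' A <- additive_relationship_matrix(trio)
#' A$matrix["F", "C"] # 0.5
#' @export
additive_relationship_matrix <- function(ped) {
  ord <- topological_order(ped)
  n <- length(ord)
  pos <- seq_len(n); names(pos) <- ord
  fi <- ifelse(is.na(ped$father), 0L, pos[ped$father])[match(ord, ped$id)]
  mi <- ifelse(is.na(ped$mother), 0L, pos[ped$mother])[match(ord, ped$id)]
  # the tabular recursion runs dense within each connected component
  # (family); components are assembled into one sparse matrix, so cohorts
  # of many independent families stay linear in total size
  child <- which(fi > 0L | mi > 0L)
  memb <- graph_components(n, c(child[fi[child] > 0L], child[mi[child] > 0L]),
                           c(fi[child][fi[child] > 0L],
                             mi[child][mi[child] > 0L]))
  ii <- list(); jj <- list(); xx <- list()
  for (comp in split(seq_len(n), memb)) {
    loc <- integer(n); loc[comp] <- seq_along(comp)
    Ab <- tabular_A(ifelse(fi[comp] > 0L, loc[pmax(fi[comp], 1L)], 0L),
                    ifelse(mi[comp] > 0L, loc[pmax(mi[comp], 1L)], 0L))
    nz <- which(Ab != 0 & upper.tri(Ab, diag = TRUE), arr.ind = TRUE)
    ii[[length(ii) + 1]] <- comp[nz[, 1]]
    jj[[length(jj) + 1]] <- comp[nz[, 2]]
    xx[[length(xx) + 1]] <- Ab[nz]
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(xx), dims = c(n, n),
                            symmetric = TRUE)
  dimnames(A) <- list(ord, ord)
  relationship_structure(ord, A, "additive")
}

relationship_structure <- function(ids, matrix, kind) {
  m <- Matrix::Matrix(matrix, sparse = TRUE)
  m <- methods::as(Matrix::forceSymmetric(m), "symmetricMatrix")
  dimnames(m) <- list(ids, ids)
  structure(list(ids = ids, matrix = m, kind = kind),
            class = "relationship_structure")
}

#' @exportS3Method base::print
print.relationship_structure <- function(x, ...) {
  cat("<relationship_structure> kind=", x$kind, ", ", length(x$ids),
      " individuals, ", Matrix::nnzero(x$matrix), " nonzero entries\n",
      sep = "")
  invisible(x)
}

#' Inbreeding coefficients from an additive relationship structure
#'
#' `F_i = A[i,i] - 1`.
#'
#' @param A a `relationship_structure` of kind `"additive"`.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(A) {
  stopifnot(inherits(A, "relationship_structure"))
  if (A$kind != "additive")
    stop("inbreeding coefficients are defined for the additive kind only")
  f <- Matrix::diag(A$matrix) - 1
  names(f) <- A$ids
  f
}

#' Shared-environment (group) covariance structure
#'
#' Builds the 0/1 block covariance of a partition: entry (i, j) is 1 when
#' i and j belong to the same group (couple, sibship, or household) or
#' i == j, else 0. Individuals in no group form singleton blocks. This is
#' the covariance implied by a group-level random effect with incidence
#' matrix Z: the block pattern equals Z Z' plus singleton diagonal.
#'
#' @param ped a [pedigree].
#' @param kind one of `"spouse_share"`, `"sib_share"`, `"household_share"`.
#' @return A `relationship_structure` of the requested kind, with a
#'   `groups` attribute (named list of id vectors).
#' @export
group_covariance_matrix <- function(ped,
                                    kind = c("spouse_share", "sib_share",
                                             "household_share")) {
  kind <- match.arg(kind)
  stopifnot(inherits(ped, "pedigree"))
  groups <- switch(kind,
    spouse_share = apply(ped$couples, 1, c, simplify = FALSE),
    sib_share = unname(ped$sibships),
    household_share = unname(ped$households))
  groups <- Filter(function(g) length(g) > 0, groups)
  seen <- unlist(groups)
  if (anyDuplicated(seen))
    stop("individual(s) in more than one ", kind, " group: ",
         paste(unique(seen[duplicated(seen)]), collapse = ", "))
  n <- length(ped$id)
  pos <- seq_len(n); names(pos) <- ped$id
  ii <- integer(0); jj <- integer(0)
  for (g in groups) {
    gi <- unname(pos[g])
    pr <- expand.grid(gi, gi)
    keep <- pr[, 1] < pr[, 2]
    ii <- c(ii, pr[keep, 1]); jj <- c(jj, pr[keep, 2])
  }
  m <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = 1, dims = c(n, n), symmetric = TRUE)
  out <- relationship_structure(ped$id, m, kind)
  attr(out, "groups") <- groups
  out
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: the inverse of A is assembled
#' directly from the pedigree using per-individual Mendelian-sampling
#' variances `d_i` (0.5 - 0.25 (F_f + F_m) with both parents known,
#' 0.75 - 0.25 F_p with one, 1 with none).
#'
#' @param ped a [pedigree].
#' @return sparse symmetric matrix A-inverse with ids in topological order.
#' @export
additive_relationship_inverse <- function(ped) {
  A <- additive_relationship_matrix(ped)
  ord <- A$ids
  Fcoef <- inbreeding_coefficients(A)
  n <- length(ord)
  pos <- seq_len(n); names(pos) <- ord
  fi <- ifelse(is.na(ped$father), 0L, pos[ped$father])[match(ord, ped$id)]
  mi <- ifelse(is.na(ped$mother), 0L, pos[ped$mother])[match(ord, ped$id)]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, min(i, j)); jj <<- c(jj, max(i, j)); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    par <- c(fi[i], mi[i]); par <- par[par > 0L]
    d <- switch(length(par) + 1L,
                1,
                0.75 - 0.25 * Fcoef[par],
                0.5 - 0.25 * sum(Fcoef[par]))
    a <- 1 / d
    add(i, i, a)
    for (p in par) add(i, p, -0.5 * a)
    if (length(par) == 1L) add(par, par, 0.25 * a)
    if (length(par) == 2L) {
      add(par[1], par[1], 0.25 * a)
      add(par[2], par[2], 0.25 * a)
      add(par[1], par[2], 0.25 * a)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               symmetric = TRUE)
  dimnames(Ainv) <- list(ord, ord)
  Ainv
}
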