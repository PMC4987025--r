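# Independent oracles used across the suite.

# Naive recursive coancestry (kinship): phi(i, j) with memoisation over a
# parent map; A = 2 * phi. Deliberately independent of the tabular-method
# implementation.
kinship_oracle <- function(ped) {
  n <- length(ped$id)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fi <- ifelse(is.na(ped$father), 0L, idx[ped$father])
  mi <- ifelse(is.na(ped$mother), 0L, idx[ped$mother])
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    # ensure the younger (descendant-side) individual is expanded; use
    # generation depth to avoid infinite recursion
    val <- if (i == j) {
      0.5 * (1 + phi(fi[i], mi[i]))
    } else {
      a <- if (depth[i] >= depth[j]) i else j
      b <- if (depth[i] >= depth[j]) j else i
      0.5 * (phi(fi[a], b) + phi(mi[a], b))
    }
    memo[[key]] <- val
    val
  }
  depth <- integer(n)
  repeat {
    nd <- ifelse(fi > 0L, depth[pmax(fi, 1L)] + 1L, 0L)
    nd <- pmax(nd, ifelse(mi > 0L, depth[pmax(mi, 1L)] + 1L, 0L))
    if (all(nd == depth)) break
    depth <- nd
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in idx) for (j in idx[idx >= i]) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# Random small pedigree: founders plus up to two further generations of
# matings among existing members and immigrants.
random_pedigree <- function(max_members = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- sample(2:4, 1)
  id <- paste0("p", seq_len(nf))
  father <- rep(NA_character_, nf)
  mother <- rep(NA_character_, nf)
  sex <- rep(c("male", "female"), length.out = nf)
  cnt <- nf
  for (gen in 1:2) {
    males <- id[sex == "male"]
    females <- id[sex == "female"]
    if (!length(males) || !length(females)) break
    n_mat <- sample(1:2, 1)
    for (k in seq_len(n_mat)) {
      if (cnt >= max_members) break
      f <- sample(males, 1)
      m <- sample(females, 1)
      noff <- sample(1:3, 1)
      for (o in seq_len(noff)) {
        if (cnt >= max_members) break
        cnt <- cnt + 1
        id <- c(id, paste0("p", cnt))
        father <- c(father, f)
        mother <- c(mother, m)
        sex <- c(sex, sample(c("male", "female"), 1))
      }
    }
  }
  pedigree(id, father, mother, sex)
}

# Small three-generation family cohort for model fits in unit tests.
test_cohort <- function(n_families = 150, seed = 1,
                        truth = simulation_truth()) {
  ped <- simulate_pedigree(cohort_design(n_families = n_families,
                                         generations = 3),
                           seed = seed)
  phen <- simulate_phenotypes(ped, truth, seed = seed + 1000)
  list(ped = ped, phen = phen, truth = truth,
       structures = list(
         additive = additive_relationship_matrix(ped),
         spouse = group_covariance_matrix(ped, "spouse_share"),
         sib = group_covariance_matrix(ped, "sib_share"),
         household = group_covariance_matrix(ped, "household_share")))
}
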