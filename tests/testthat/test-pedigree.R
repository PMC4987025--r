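test_that("pedigree parsing, validation and derived groupings", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("id\tfather\tmother\tsex",
               "F\t0\t0\tm", "M\t0\t0\tf", "C\tF\tM\tf"), tmp)
  ped <- parse_pedigree(tmp)
  expect_length(ped$id, 3)
  expect_equal(ped$sibships, list(`F|M` = "C"))
  expect_equal(sort(ped$couples[1, ]), c("F", "M"), ignore_attr = TRUE)

  # founders only: no couples, no sibships
  writeLines(c("id\tfather\tmother\tsex",
               "A\t0\t0\tm", "B\t0\t0\tf", "D\t0\t0\tf"), tmp)
  ped0 <- parse_pedigree(tmp)
  expect_equal(nrow(ped0$couples), 0)
  expect_length(ped0$sibships, 0)

  # structural errors
  expect_error(pedigree(c("X", "Y"), c("Y", "X"), c(NA, NA)),
               "cycle")
  expect_error(pedigree(c("A", "B"), c("Z", NA), c(NA, NA)),
               "unknown parent")
  expect_error(pedigree(c("A", "A"), c(NA, NA), c(NA, NA)),
               "duplicate")
})

test_that("topological order puts parents before offspring", {
  ped <- pedigree(c("D", "C", "B", "A"),
                  father = c("C", "B", "A", NA),
                  mother = c(NA, NA, NA, NA))
  expect_equal(topological_order(ped), c("A", "B", "C", "D"))
  founders <- pedigree(c("z", "q", "a"), rep(NA, 3), rep(NA, 3))
  expect_equal(topological_order(founders), c("z", "q", "a"))
})

test_that("additive relationship matrix: worked cases", {
  founders <- pedigree(c("a", "b", "c"), rep(NA, 3), rep(NA, 3))
  A0 <- additive_relationship_matrix(founders)
  expect_equal(as.matrix(A0$matrix), diag(3), ignore_attr = TRUE)

  trio <- pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"))
  A <- additive_relationship_matrix(trio)$matrix
  expect_equal(A["F", "C"], 0.5)
  expect_equal(A["M", "C"], 0.5)
  expect_equal(A["C", "C"], 1)
  expect_equal(A["F", "M"], 0)

  # full sibs mated: A_S1S2 = 0.5, offspring inbred with A_KK = 1.25
  ped <- pedigree(c("P", "Q", "S1", "S2", "K"),
                  c(NA, NA, "P", "P", "S1"),
                  c(NA, NA, "Q", "Q", "S2"))
  A2 <- additive_relationship_matrix(ped)$matrix
  expect_equal(A2["S1", "S2"], 0.5)
  expect_equal(A2["K", "K"], 1.25)
  Fc <- inbreeding_coefficients(additive_relationship_matrix(ped))
  expect_equal(unname(Fc["K"]), 0.25)
  expect_equal(unname(Fc[c("P", "Q", "S1", "S2")]), rep(0, 4))
})

test_that("tabular A equals the recursive-coancestry oracle on random pedigrees", {
  for (s in 1:25) {
    ped <- random_pedigree(max_members = 20, seed = 100 + s)
    A <- additive_relationship_matrix(ped)
    Ao <- kinship_oracle(ped)
    expect_equal(as.matrix(A$matrix)[ped$id, ped$id], Ao,
                 tolerance = 1e-12, ignore_attr = TRUE)
    # PSD up to numerical tolerance
    ev <- eigen(as.matrix(A$matrix), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    # inbreeding from the oracle diagonal
    expect_equal(unname(inbreeding_coefficients(A)[ped$id]),
                 unname(diag(Ao) - 1), tolerance = 1e-12)
  }
})

test_that("A matrix is invariant to input row permutation", {
  ped <- random_pedigree(max_members = 15, seed = 7)
  perm <- sample(length(ped$id))
  ped2 <- pedigree(ped$id[perm], ped$father[perm], ped$mother[perm],
                   ped$sex[perm])
  A1 <- additive_relationship_matrix(ped)
  A2 <- additive_relationship_matrix(ped2)
  expect_equal(as.matrix(A1$matrix)[ped$id, ped$id],
               as.matrix(A2$matrix)[ped$id, ped$id])
})

test_that("Henderson sparse inverse matches the dense inverse of A", {
  ped <- pedigree(c("P", "Q", "S1", "S2", "K"),
                  c(NA, NA, "P", "P", "S1"),
                  c(NA, NA, "Q", "Q", "S2"))
  A <- additive_relationship_matrix(ped)
  Ainv <- additive_relationship_inverse(ped)
  prod <- as.matrix(Ainv %*% A$matrix[rownames(Ainv), colnames(Ainv)])
  expect_equal(prod, diag(5), tolerance = 1e-10, ignore_attr = TRUE)
  for (s in 1:5) {
    pedr <- random_pedigree(max_members = 18, seed = 300 + s)
    Ar <- additive_relationship_matrix(pedr)
    Ai <- additive_relationship_inverse(pedr)
    prod <- as.matrix(Ai %*% Ar$matrix[rownames(Ai), colnames(Ai)])
    expect_equal(prod, diag(length(pedr$id)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("group covariance structures are 0/1 partition blocks", {
  ped <- pedigree(c("F", "M", "C1", "C2", "C3", "Z"),
                  c(NA, NA, "F", "F", "F", NA),
                  c(NA, NA, "M", "M", "M", NA),
                  sex = c("m", "f", "f", "m", "f", "m"))
  sp <- group_covariance_matrix(ped, "spouse_share")$matrix
  expect_equal(sp["F", "M"], 1)
  expect_equal(sp["F", "Z"], 0)
  expect_equal(Matrix::diag(sp), rep(1, 6), ignore_attr = TRUE)

  sib <- group_covariance_matrix(ped, "sib_share")$matrix
  expect_equal(as.matrix(sib[c("C1", "C2", "C3"), c("C1", "C2", "C3")]),
               matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(sum(sib), 9 + 3) # sib block plus singleton diagonal

  # no households: identity
  hh <- group_covariance_matrix(ped, "household_share")$matrix
  expect_equal(as.matrix(hh), diag(6), ignore_attr = TRUE)

  # projection property of the partition: entries 0/1, idempotent blocks
  M <- as.matrix(sib)
  expect_true(all(M %in% c(0, 1)))
  blocksum <- M %*% M
  expect_true(all(blocksum[M == 0] == 0))
})

test_that("relationship structures round-trip through coordinate text", {
  ped <- random_pedigree(max_members = 12, seed = 11)
  A <- additive_relationship_matrix(ped)
  f <- tempfile()
  write_relationship(A, f)
  A2 <- read_relationship(f)
  expect_equal(A2$ids, A$ids)
  expect_equal(as.matrix(A2$matrix), as.matrix(A$matrix),
               tolerance = 1e-12)
  expect_equal(A2$kind, "additive")
})
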