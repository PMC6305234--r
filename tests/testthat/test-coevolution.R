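make_msa <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  demotif::read_msa(write_fasta(stats::setNames(rows, ids)), "afa")
}

test_that("gap filtering is per-sequence and boundary inclusive", {
  msa <- make_msa(c("ACDEFGHIKL",
                    "AC-EF-HIK-",   # 3/10 gaps -> removed at 0.2
                    "ACDEF-HIK-",   # 2/10 gaps -> kept (boundary)
                    "ACDEFGHIKL"))
  kept <- filter_by_gap(msa, 0.2)
  expect_equal(kept$ids, c("s1", "s3", "s4"))  # order preserved
  expect_identical(filter_by_gap(msa, 1.0)$ids, msa$ids)  # identity
  expect_error(filter_by_gap(make_msa("----------"), 0.2), "threshold")
})

test_that("consensus takes the most common non-gap residue, ties alphabetic", {
  msa <- make_msa(c("AAW", "ACW", "C-W"))
  # col1 A,A,C -> A; col2 A,C (tie) -> A; col3 gaps ignored -> W
  expect_equal(build_consensus(msa), "AAW")
  expect_equal(build_consensus(make_msa(c("-", "-"))), "X")  # all-gap
})

test_that("binarization matches hand enumeration", {
  msa <- make_msa(c("ACDE", "ACDA", "----", "ACDE"))
  b <- binarize(msa, consensus = "ACDE")
  expect_equal(unname(b$matrix[1, ]), c(1, 1, 1, 1))
  expect_equal(unname(b$matrix[2, ]), c(1, 1, 1, 0))
  expect_equal(unname(b$matrix[3, ]), c(0, 0, 0, 0))  # gap row -> all 0
  expect_equal(unname(b$f), c(0.75, 0.75, 0.75, 0.5))
  expect_error(binarize(msa, consensus = "ACD"), "length")
})

test_that("plain coupling is |f_ij - f_i f_j| with zeroed constant columns", {
  # two identical columns with f = 0.5 -> coupling 0.25
  b <- structure(list(matrix = cbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                     c(1, 1, 1, 1)),
                      consensus = "AAA", f = c(0.5, 0.5, 1),
                      kept_ids = paste0("s", 1:4)), class = "de_binmsa")
  cp <- coupling_matrix(b)
  expect_equal(cp$C[1, 2], 0.25)
  expect_equal(cp$C[1, 3], 0)     # constant column
  expect_equal(cp$C[3, 2], 0)
  expect_equal(diag(cp$C), rep(0, 3))
  expect_error(coupling_matrix(structure(list(matrix = b$matrix[1, ,
    drop = FALSE]), class = "de_binmsa")), "2 sequences")
})

test_that("independent columns decouple as n grows", {
  set.seed(31)
  M <- matrix(stats::rbinom(10000 * 2, 1, 0.5), ncol = 2)
  b <- structure(list(matrix = M, f = colMeans(M)), class = "de_binmsa")
  expect_lt(coupling_matrix(b)$C[1, 2], 0.02)
})

test_that("coupling matrix is symmetric and permutation invariant", {
  msa <- gen_msa(msa_gen_config(n_seq = 60, n_col = 20,
                                planted_pairs = list(c(3L, 12L)), seed = 8))
  b <- binarize(msa)
  C1 <- coupling_matrix(b)$C
  expect_equal(C1, t(C1))
  perm <- sample(length(msa$ids))
  msa_p <- make_msa(unname(msa$rows[perm]), ids = msa$ids[perm])
  C2 <- coupling_matrix(binarize(msa_p, b$consensus))$C
  expect_equal(C1, C2, tolerance = 1e-12)
})

test_that("duplicating a column attains the maximal coupling for its f", {
  set.seed(32)
  col <- stats::rbinom(200, 1, 0.6)
  M <- cbind(col, col, stats::rbinom(200, 1, 0.5))
  b <- structure(list(matrix = M, f = colMeans(M)), class = "de_binmsa")
  f1 <- mean(col)
  expect_equal(coupling_matrix(b)$C[1, 2], abs(f1 - f1^2))
})

test_that("top_partners ranks a planted pair first and flags it", {
  msa <- gen_msa(msa_gen_config(n_seq = 400, n_col = 40,
                                planted_pairs = list(c(7L, 31L)),
                                rho = 0.9, seed = 9))
  cp <- coupling_matrix(binarize(filter_by_gap(msa)))
  tp <- top_partners(cp, 7L, k = 5)
  expect_equal(tp$partner[1], 31L)
  expect_true(tp$relation[1])
  # k larger than n_col - 1 returns everything
  expect_equal(nrow(top_partners(cp, 7L, k = 100)), 39L)
  expect_error(top_partners(cp, 41L), "out of range")
})

test_that("sca_weighted mode applies positional weights", {
  msa <- gen_msa(msa_gen_config(n_seq = 100, n_col = 10,
                                planted_pairs = list(c(2L, 8L)), seed = 10))
  b <- binarize(msa)
  plain <- coupling_matrix(b, "plain")
  wtd <- coupling_matrix(b, "sca_weighted", qbar = 0.05)
  phi <- abs(log(b$f * 0.95 / (0.05 * (1 - b$f))))
  phi[b$f <= 0 | b$f >= 1] <- 0
  expect_equal(wtd$C, plain$C * outer(phi, phi), tolerance = 1e-12)
})

test_that("residue positions map through gaps to alignment columns", {
  msa <- make_msa(c("AMDEK", "A-DEK"), ids = c("u", "g"))
  # ungapped row: columns equal positions
  m1 <- map_de_to_columns("u", msa, 2L)
  expect_equal(m1$d_col, 2L)
  expect_equal(m1$e_col, 3L)
  # gapped row "A-DE": residues A,D,E,K; DE at residues 1-2 -> columns 2-3
  m2 <- map_de_to_columns("g", msa, 1L)
  expect_equal(m2$d_col, 2L)
  expect_equal(m2$e_col, 3L)
  expect_error(map_de_to_columns("g", msa, 9L), "out of range")
  expect_error(map_de_to_columns("u", msa, 0L), "not DE")
  expect_error(map_de_to_columns("nope", msa, 1L), "not present")
})
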