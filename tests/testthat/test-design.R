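test_that("base matrix is filled column-wise with null cells masked", {
  P <- base_matrix(25, 5)
  expect_identical(P[1, 1], 1L)
  expect_identical(P[5, 5], 25L)
  expect_identical(P[2, 3], (3L - 1L) * 5L + 2L)
  expect_false(anyNA(P))

  expect_identical(base_matrix(4, 2), matrix(c(1L, 2L, 3L, 4L), 2, 2))

  P23 <- base_matrix(23, 5)  # values 24, 25 are unassociated
  expect_identical(sum(is.na(P23)), 2L)
  expect_true(all(is.na(P23[4:5, 5])))
})

test_that("shift amounts follow ((i-1)*k) mod p", {
  expect_identical(shift_amount(2, 1, 5), 1L)
  expect_identical(shift_amount(3, 1, 5), 2L)
  for (p in c(3L, 5L, 7L)) {
    for (k in seq_len(p - 1L)) {
      expect_identical(shift_amount(1, k, p), 0L)  # column 1 never shifts
      expect_identical(shift_amount(seq_len(p), k, p),
                       as.integer(((seq_len(p) - 1L) * k) %% p))
    }
  }
  expect_error(shift_amount(2, 0, 5), "k")
  expect_error(shift_amount(2, 5, 5), "1 ... p-1")
  expect_error(shift_amount(6, 1, 5), "1 ... p")
})

test_that("shifted matrices rotate columns conveyor-belt fashion", {
  P <- base_matrix(25, 5)
  P1 <- shifted_matrix(P, 1)
  # last element of column 2 of P_1 is the first element of column 2 of P
  expect_identical(P1[5, 2], P[1, 2])
  expect_identical(P1[5, 2], 6L)
  # last two elements of column 3 of P_1 are the first two of column 3 of P
  expect_identical(P1[4:5, 3], P[1:2, 3])
  # column 1 is invariant under any shift level
  for (k in 1:4) expect_identical(shifted_matrix(P, k)[, 1], P[, 1])
  P7 <- base_matrix(49, 7)
  for (k in c(1L, 3L, 6L)) {
    Pk <- shifted_matrix(P7, k)
    expect_identical(Pk[, 1], P7[, 1])
    for (i in 2:7) {
      r <- shift_amount(i, k, 7)
      expect_identical(Pk[, i], P7[c((r + 1L):7L, seq_len(r)), i])
    }
  }
})

test_that("the n = 4 design is the six worked subsets", {
  d <- enumerate_subsets(4)
  expect_length(d$subsets, 6L)
  expect_identical(d$subsets,
                   list(c(1L, 2L), c(3L, 4L),    # columns of P
                        c(1L, 3L), c(2L, 4L),    # rows of P
                        c(1L, 4L), c(2L, 3L)))   # rows of P_1
  expect_identical(d$provenance$allows_self_comparison,
                   c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("subset counts, sizes and provenance match the construction", {
  d <- enumerate_subsets(25)
  expect_length(d$subsets, 30L)  # p^2 + p
  expect_true(all(lengths(d$subsets) == 5L))
  expect_identical(table(d$provenance$source),
                   table(factor(c(rep("column-of-P", 5), rep("row-of-P", 5),
                                  rep("row-of-Pk", 20)))))
  expect_identical(sort(unique(d$provenance$k)), 1:4)

  d23 <- enumerate_subsets(23)  # null cells shrink some subsets
  expect_length(d23$subsets, 30L)
  expect_true(all(lengths(d23$subsets) <= 5L))
  expect_true(all(unlist(d23$subsets) >= 1L & unlist(d23$subsets) <= 23L))
  expect_identical(sum(lengths(d23$subsets)), 23L * 6L)  # each in p+1 subsets
})

test_that("every individual belongs to exactly p + 1 subsets", {
  for (n in c(4L, 23L, 25L, 50L, 100L)) {
    d <- enumerate_subsets(n)
    counts <- tabulate(unlist(d$subsets), nbins = n)
    expect_true(all(counts == d$p + 1L), info = paste("n =", n))
  }
  d <- enumerate_subsets(4)
  m1 <- membership(d, 1L)
  expect_length(m1, 3L)  # p + 1 = 3: its column, its row, its P_1 row
  expect_identical(m1, c(0L, 2L, 4L))
  expect_length(membership(enumerate_subsets(25), 25L), 6L)
  expect_error(membership(d, 5L), "1 ... n")
  expect_error(membership(d, 0L), ">= 1")
})

test_that("comparison counts conserve the naive all-pairs total", {
  d25 <- enumerate_subsets(25)
  expect_identical(comparison_count(d25), 300)           # 30 x C(5,2)
  expect_identical(comparison_count(d25), (5^4 - 5^2) / 2)
  expect_identical(comparison_count(d25, include_self = TRUE), 325)
  expect_identical(comparison_count(enumerate_subsets(4)), 6)
  for (n in c(4L, 23L, 25L, 49L, 50L, 360L)) {  # p^2 = n and p^2 > n cases
    d <- enumerate_subsets(n)
    expect_identical(comparison_count(d), (as.double(n)^2 - n) / 2,
                     info = paste("n =", n))
    expect_identical(comparison_count(d, TRUE),
                     (as.double(n)^2 + n) / 2, info = paste("n =", n))
  }
})

test_that("the construction is deterministic", {
  expect_identical(enumerate_subsets(97), enumerate_subsets(97))
})

test_that("invalid inputs are rejected and composite orders warn", {
  expect_error(enumerate_subsets(3), ">= 4")
  expect_error(enumerate_subsets(25, p = 4), "at least")
  expect_warning(d <- enumerate_subsets(16, p = 4), "composite")
  expect_false(d$p_is_prime)
})

test_that("subset access by id and subset dropping behave", {
  d <- enumerate_subsets(25)
  expect_identical(subset_members(d, 0L), 1:5)
  expect_error(subset_members(d, 30L), "0 ...")
  d2 <- drop_subset(d, 7L)
  expect_length(d2$subsets, 29L)
  expect_false(7L %in% d2$provenance$subset_id)
  expect_error(drop_subset(d2, 7L), "no subset")
})
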