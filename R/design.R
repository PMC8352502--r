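# Affine-plane partition design: p^2 + p subsets of <= p individuals such
# that every unordered pair of individuals co-occurs in exactly one subset.

#' Base matrix of the design
#'
#' Places the numbers `1 ... p^2` column-wise into a `p`-by-`p` matrix; cell
#' `(j, i)` (row, column, 1-based) holds `(i-1)*p + j`. Values greater than
#' `n` index no individual and are masked as `NA` ("null" cells), which is
#' what allows the construction to serve sample sizes strictly below `p^2`.
#'
#' @param n Number of individuals (>= 4).
#' @param p Design order; normally `smallest_admissible_prime(n)`. Any
#'   `p >= 2` with `p^2 >= n` is accepted so that the effect of a composite
#'   order can be demonstrated.
#' @return A `p`-by-`p` integer matrix with `NA` in null cells.
#' @examples
#' base_matrix(4, 2)   # matrix(c(1, 2, 3, 4), 2, 2)
#' base_matrix(23, 5)  # values 24, 25 are NA
#' @export
base_matrix <- function(n, p) {
  n <- check_count(n, 4L, "n")
  p <- check_count(p, 2L, "p")
  if (as.double(p)^2 < n) {
    stop("`p`^2 must be at least `n` (p = ", p, ", n = ", n, ")", call. = FALSE)
  }
  P <- matrix(seq_len(p * p), nrow = p)  # column-wise fill
  P[P > n] <- NA_integer_
  P
}

#' Cyclic shift amount for a shifted matrix column
#'
#' For shift level `k` (1 ... p-1), column `i` of the shifted matrix `P_k` is
#' rotated relative to column `i` of the base matrix by
#' `r(i, k) = ((i - 1) * k) mod p` rows.
#'
#' @param i Column index (or vector of indices) in `1 ... p`.
#' @param k Shift level in `1 ... p-1`.
#' @param p Design order.
#' @return Integer shift(s) in `0 ... p-1`.
#' @examples
#' shift_amount(2, 1, 5)  # 1
#' shift_amount(3, 1, 5)  # 2
#' @export
shift_amount <- function(i, k, p) {
  p <- check_count(p, 2L, "p")
  k <- check_count(k, 1L, "k")
  if (k > p - 1L) {
    stop("`k` must be in 1 ... p-1 (shifted matrices are defined only there)",
         call. = FALSE)
  }
  if (!is.numeric(i) || length(i) < 1L || anyNA(i) ||
      any(i != trunc(i)) || any(i < 1L) || any(i > p)) {
    stop("`i` must be column indices in 1 ... p", call. = FALSE)
  }
  as.integer(((as.integer(i) - 1L) * k) %% p)
}

#' Shifted matrix P_k
#'
#' Rotates each column `i` of the base matrix cyclically by `r(i, k)` rows,
#' so that `P_k[j, i] = P[((j - 1 + r(i, k)) mod p) + 1, i]`: column contents
#' move conveyor-belt fashion, e.g. for `k = 1` the last element of column 2
#' of `P_1` equals the first element of column 2 of `P`.
#'
#' @param P Base matrix from [base_matrix()].
#' @param k Shift level in `1 ... p-1`.
#' @return A `p`-by-`p` integer matrix.
#' @examples
#' P <- base_matrix(25, 5)
#' shifted_matrix(P, 1)[5, 2] == P[1, 2]
#' @export
shifted_matrix <- function(P, k) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("`P` must be a square matrix from base_matrix()", call. = FALSE)
  }
  p <- nrow(P)
  r <- shift_amount(seq_len(p), k, p)
  rows <- (rep(seq_len(p) - 1L, times = p) + rep(r, each = p)) %% p + 1L
  matrix(P[cbind(rows, rep(seq_len(p), each = p))], p, p)
}

#' Enumerate the subsets of the partition design
#'
#' Builds the full design for `n` individuals: in order, the `p` columns of
#' the base matrix `P`, the `p` rows of `P`, then for each shift level
#' `k = 1 ... p-1` the `p` rows of the shifted matrix `P_k` — `p^2 + p`
#' subsets in total. Null cells are dropped from the member lists, so when
#' `p^2 > n` some subsets hold fewer than `p` individuals (possibly fewer
#' than two). Each individual belongs to exactly `p + 1` subsets and every
#' unordered pair of individuals co-occurs in exactly one subset (verifiable
#' with [pair_coverage()]).
#'
#' Self-comparisons, when an application wants them, are restricted to the
#' first `p` subsets (the columns of `P`): each individual appears in exactly
#' one column, so the self-pair is counted exactly once.
#'
#' @param n Number of individuals (>= 4). Individuals are indexed `1 ... n`.
#' @param p Expert override of the design order, intended for negative
#'   controls; a warning is issued when `p` is composite because pair
#'   coverage is then no longer exact-once. Default: the smallest prime with
#'   `p^2 >= n`.
#' @return A `partition_design` object: a list with elements `n`, `p`,
#'   `p_is_prime`, `index_base` (always 1), `subsets` (list of sorted integer
#'   member vectors, in design order), and `provenance` (a data frame with
#'   one row per subset: `subset_id` (0-based ordinal), `source` (one of
#'   `"column-of-P"`, `"row-of-P"`, `"row-of-Pk"`), `index` (which column or
#'   row), `k` (shift level, `NA` for subsets drawn from `P`), `size`, and
#'   `allows_self_comparison`).
#' @examples
#' d <- enumerate_subsets(4)
#' d$subsets  # {1,2}, {3,4}, {1,3}, {2,4}, {1,4}, {2,3}
#' @export
enumerate_subsets <- function(n, p = NULL) {
  n <- check_count(n, 4L, "n")
  if (is.null(p)) {
    p <- smallest_admissible_prime(n)
  } else {
    p <- check_count(p, 2L, "p")
    if (as.double(p)^2 < n) {
      stop("`p`^2 must be at least `n`", call. = FALSE)
    }
    if (!is_prime(p)) {
      warning("p = ", p, " is composite: exact-once pair coverage is not ",
              "guaranteed for this design", call. = FALSE)
    }
  }
  P <- base_matrix(n, p)
  n_sub <- p * (p + 1L)
  subsets <- vector("list", n_sub)
  src <- character(n_sub)
  idx <- integer(n_sub)
  kk <- rep(NA_integer_, n_sub)

  strip <- function(v) sort.int(v[!is.na(v)], method = "radix")

  for (i in seq_len(p)) subsets[[i]] <- strip(P[, i])
  src[seq_len(p)] <- "column-of-P"
  idx[seq_len(p)] <- seq_len(p)

  for (j in seq_len(p)) subsets[[p + j]] <- strip(P[j, ])
  src[p + seq_len(p)] <- "row-of-P"
  idx[p + seq_len(p)] <- seq_len(p)

  off <- 2L * p
  for (k in seq_len(p - 1L)) {
    Pk <- shifted_matrix(P, k)
    for (j in seq_len(p)) subsets[[off + j]] <- strip(Pk[j, ])
    src[off + seq_len(p)] <- "row-of-Pk"
    idx[off + seq_len(p)] <- seq_len(p)
    kk[off + seq_len(p)] <- k
    off <- off + p
  }

  provenance <- data.frame(
    subset_id = seq_len(n_sub) - 1L,
    source = src,
    index = idx,
    k = kk,
    size = lengths(subsets),
    allows_self_comparison = c(rep(TRUE, p), rep(FALSE, n_sub - p)),
    stringsAsFactors = FALSE
  )

  structure(
    list(n = n, p = p, p_is_prime = is_prime(p), index_base = 1L,
         subsets = subsets, provenance = provenance),
    class = "partition_design"
  )
}

#' @export
print.partition_design <- function(x, ...) {
  sizes <- lengths(x$subsets)
  cat("Affine-plane partition design\n")
  cat("  individuals (n):", x$n, "\n")
  cat("  order (p):      ", x$p,
      if (x$p_is_prime) "(prime)" else "(COMPOSITE - coverage not exact)", "\n")
  cat("  subsets:        ", length(x$subsets), " (= p^2 + p)\n", sep = "")
  cat("  subset sizes:   ", min(sizes), "-", max(sizes), "\n", sep = "")
  cat("  memberships:     each individual in p + 1 =", x$p + 1L, "subsets\n")
  cat("  comparisons:    ", format(comparison_count(x), big.mark = ","),
      "(pairwise, excluding self)\n")
  invisible(x)
}

#' Members of one subset
#'
#' @param design A `partition_design`.
#' @param subset_id 0-based subset ordinal, as used in provenance, keep-file
#'   names and job manifests.
#' @return Sorted integer vector of member indices.
#' @export
subset_members <- function(design, subset_id) {
  stopifnot(inherits(design, "partition_design"))
  subset_id <- check_count(subset_id, 0L, "subset_id")
  if (subset_id >= length(design$subsets)) {
    stop("`subset_id` must be in 0 ... ", length(design$subsets) - 1L,
         call. = FALSE)
  }
  design$subsets[[subset_id + 1L]]
}

#' Subsets containing one individual
#'
#' Every individual belongs to exactly `p + 1` subsets: its column of `P`,
#' its row of `P`, and one row of each shifted matrix `P_k`.
#'
#' @param design A `partition_design`.
#' @param individual Individual index in `1 ... n`.
#' @return Integer vector of `p + 1` distinct 0-based subset ids.
#' @export
membership <- function(design, individual) {
  stopifnot(inherits(design, "partition_design"))
  individual <- check_count(individual, 1L, "individual")
  if (individual > design$n) {
    stop("`individual` must be in 1 ... n = ", design$n, call. = FALSE)
  }
  hit <- vapply(design$subsets, function(s) any(s == individual), logical(1))
  design$provenance$subset_id[hit]
}

#' Total number of comparisons implied by a design
#'
#' Sums `m * (m - 1) / 2` over subsets of size `m`; because every pair
#' co-occurs exactly once, this equals the naive all-pairs total
#' `(n^2 - n) / 2`, and when `p^2 = n` it also equals `(p^4 - p^2) / 2`.
#' With `include_self = TRUE`, one self-comparison per individual is added by
#' counting members of the first `p` subsets only (each individual sits in
#' exactly one column of `P`).
#'
#' @param design A `partition_design`.
#' @param include_self Also count one self-comparison per individual?
#' @return A double (counts overflow integers for large `n`).
#' @examples
#' comparison_count(enumerate_subsets(25))        # 300
#' comparison_count(enumerate_subsets(25), TRUE)  # 325
#' @export
comparison_count <- function(design, include_self = FALSE) {
  stopifnot(inherits(design, "partition_design"))
  m <- as.double(lengths(design$subsets))
  total <- sum(m * (m - 1) / 2)
  if (isTRUE(include_self)) {
    total <- total + sum(m[design$provenance$allows_self_comparison])
  }
  total
}

#' Remove one subset from a design
#'
#' Produces a deliberately broken design for negative controls: the pairs
#' that co-occurred only in the removed subset are no longer covered, which
#' [pair_coverage()] and [equivalence_check()] both detect.
#'
#' @param design A `partition_design`.
#' @param subset_id 0-based id of the subset to drop.
#' @return A `partition_design` with one fewer subset (other ids unchanged).
#' @export
drop_subset <- function(design, subset_id) {
  stopifnot(inherits(design, "partition_design"))
  subset_id <- check_count(subset_id, 0L, "subset_id")
  pos <- match(subset_id, design$provenance$subset_id)
  if (is.na(pos)) stop("no subset with id ", subset_id, call. = FALSE)
  design$subsets <- design$subsets[-pos]
  design$provenance <- design$provenance[-pos, , drop = FALSE]
  rownames(design$provenance) <- NULL
  design
}
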