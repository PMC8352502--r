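# Brute-force verification that a design covers every unordered pair of
# individuals exactly once. Deliberately independent of the construction in
# design.R: it consumes only the emitted member lists.

#' Pair co-occurrence census of a design
#'
#' Counts, for every unordered pair of individuals, the number of subsets `t`
#' in which both occur, by exhaustively walking the member lists. For a valid
#' design `t = 1` for all `n * (n - 1) / 2` pairs. The result is reported as
#' a histogram over `t` so that violations are diagnosable, with a capped
#' list of offending pairs.
#'
#' @param design A `partition_design`, or a bare list of integer member
#'   vectors (in which case `n` must be given) — e.g. subsets read back from
#'   keep-files.
#' @param n Number of individuals; taken from the design when omitted.
#' @param max_offenders Cap on the number of offending pairs reported.
#' @return A `coverage_report`: list with `n`, `p` (`NA` for bare subset
#'   lists), `histogram` (named numeric, names are `t` values), `n_offending`
#'   (total pairs with `t != 1`), `offending_pairs` (data frame `i`, `j`,
#'   `t`), and `is_exact_cover`.
#' @examples
#' pair_coverage(enumerate_subsets(25))$histogram  # c(`1` = 300)
#' @export
pair_coverage <- function(design, n = NULL, max_offenders = 100L) {
  if (inherits(design, "partition_design")) {
    subsets <- design$subsets
    n <- design$n
    p <- design$p
  } else if (is.list(design)) {
    if (is.null(n)) {
      stop("`n` is required when `design` is a bare subset list", call. = FALSE)
    }
    n <- check_count(n, 1L, "n")
    subsets <- lapply(design, as.integer)
    p <- NA_integer_
  } else {
    stop("`design` must be a partition_design or a list of member vectors",
         call. = FALSE)
  }
  max_offenders <- check_count(max_offenders, 0L, "max_offenders")
  res <- .pair_coverage_core(subsets, n, max_offenders)
  histogram <- stats::setNames(res$count, res$t)
  # exhaustiveness check: every unordered pair tallied exactly once
  stopifnot(isTRUE(all.equal(sum(histogram), n * (n - 1) / 2)))
  structure(
    list(n = n, p = p,
         histogram = histogram,
         n_offending = res$n_offending,
         offending_pairs = data.frame(i = res$off_i, j = res$off_j,
                                      t = res$off_t),
         is_exact_cover = identical(as.integer(res$t), 1L)),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Pair-coverage report (n = ", x$n, ")\n", sep = "")
  cat("  t histogram:", paste0("t=", names(x$histogram), ": ",
                               format(x$histogram, big.mark = ","),
                               collapse = "; "), "\n")
  if (x$is_exact_cover) {
    cat("  exact cover: every pair co-occurs in exactly one subset\n")
  } else {
    cat("  NOT an exact cover: ", format(x$n_offending, big.mark = ","),
        " offending pair(s); first few:\n", sep = "")
    print(head(x$offending_pairs, 5L))
  }
  invisible(x)
}

#' Coverage sweep over many sample sizes
#'
#' Builds the design and runs [pair_coverage()] for each `n`, summarizing
#' whether the exact-once property holds. By default it stops at the first
#' violation, naming the first offending pair.
#'
#' @param n_values Integer vector of sample sizes (each >= 4).
#' @param fail_fast Stop with an error on the first violation?
#' @param max_offenders Passed to [pair_coverage()].
#' @return Data frame with one row per `n`: `n`, `p`, `n_subsets`,
#'   `t_value` (the single co-occurrence count if unique, else `NA`),
#'   `is_exact_cover`.
#' @examples
#' coverage_sweep(c(4, 5, 25))
#' @export
coverage_sweep <- function(n_values, fail_fast = TRUE, max_offenders = 5L) {
  if (length(n_values) < 1L) stop("`n_values` must be non-empty", call. = FALSE)
  rows <- lapply(n_values, function(n) {
    d <- enumerate_subsets(n)
    rep <- pair_coverage(d, max_offenders = max_offenders)
    if (fail_fast && !rep$is_exact_cover) {
      off <- rep$offending_pairs[1L, ]
      stop("coverage violation at n = ", n, ": pair {", off$i, ", ", off$j,
           "} co-occurs in ", off$t, " subsets", call. = FALSE)
    }
    tv <- if (length(rep$histogram) == 1L) {
      as.integer(names(rep$histogram))
    } else {
      NA_integer_
    }
    data.frame(n = n, p = d$p, n_subsets = length(d$subsets),
               t_value = tv, is_exact_cover = rep$is_exact_cover)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
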