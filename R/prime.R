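#' Deterministic primality test
#'
#' Trial division up to the square root. Deterministic by construction; used
#' both to find the design prime and to label expert-overridden orders.
#'
#' @param x A single non-negative integer.
#' @return `TRUE` if `x` is prime.
#' @examples
#' is_prime(661)
#' is_prime(660)
#' @export
is_prime <- function(x) {
  x <- check_count(x, 0L, "x")
  if (x < 2L) return(FALSE)
  if (x < 4L) return(TRUE)
  if (x %% 2L == 0L) return(FALSE)
  d <- 3L
  while (as.double(d) * d <= x) {
    if (x %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

#' Smallest prime whose square covers the sample size
#'
#' The order of the affine-plane design: the lowest prime `p` with `p^2 >= n`.
#' Individuals `n+1 ... p^2` (if any) become unassociated null cells of the
#' base matrix, so `p^2` need not equal `n`.
#'
#' @param n Number of individuals; must be at least 4.
#' @return The design prime `p` as an integer.
#' @examples
#' smallest_admissible_prime(25)     # 5
#' smallest_admissible_prime(435187) # 661
#' @export
smallest_admissible_prime <- function(n) {
  n <- check_count(n, 4L, "n")
  p <- as.integer(ceiling(sqrt(as.double(n))))
  # guard against floating-point sqrt landing one high
  while (p > 2L && as.double(p - 1L)^2 >= n) p <- p - 1L
  if (p < 2L) p <- 2L
  while (!is_prime(p)) p <- p + 1L
  p
}
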