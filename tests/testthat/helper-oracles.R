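# Independent, deliberately naive oracles used to cross-check the package's
# own machinery at small n. They share no code with the implementation.

# Pair co-occurrence histogram by literal enumeration: encode each unordered
# pair inside each subset as a scalar key and tabulate.
r_pair_histogram <- function(subsets, n) {
  keys <- unlist(lapply(subsets, function(s) {
    s <- sort(s)
    if (length(s) < 2L) return(double())
    cp <- combn(s, 2L)
    (cp[1L, ] - 1) * n + cp[2L, ]
  }))
  tab <- table(table(keys))
  counts <- as.double(tab)
  names(counts) <- names(tab)
  n_zero <- n * (n - 1) / 2 - length(unique(keys))
  if (n_zero > 0) counts <- c(`0` = n_zero, counts)
  counts[order(as.integer(names(counts)))]
}

# Smallest prime q with q^2 >= n by scanning ascending integers with the
# schoolbook divisor test.
r_smallest_prime <- function(n) {
  naive_prime <- function(x) x >= 2L && (x < 4L || all(x %% 2:(x - 1L) != 0L))
  q <- 2L
  while (!(naive_prime(q) && q^2 >= n)) q <- q + 1L
  q
}

# Histograms as comparable named numeric vectors.
expect_same_histogram <- function(a, b) {
  a <- a[order(as.integer(names(a)))]
  b <- b[order(as.integer(names(b)))]
  expect_identical(names(a), names(b))
  expect_equal(unname(as.double(a)), unname(as.double(b)))
}

# Exact row keys for comparing segment tables (doubles at full precision).
segment_keys_for_test <- function(df) {
  if (!nrow(df)) return(character())
  do.call(paste, c(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }), sep = "|"))
}
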