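# Internal helpers shared across modules.

# Validate a scalar count (integer-valued, >= min). Returns integer.
check_count <- function(x, min, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != trunc(x)) {
    stop("`", what, "` must be a single integer", call. = FALSE)
  }
  if (x < min) {
    stop("`", what, "` must be >= ", min, " (got ", x, ")", call. = FALSE)
  }
  as.integer(x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- check_count(seed, 0L, "seed")
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
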