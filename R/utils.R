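#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm runif pf pt median setNames
#' @importFrom utils head tail
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# scalar checks used across constructors
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Row-normalize a matrix of 3-vectors to unit length.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) abort("cannot normalize a zero vector")
  m / n
}
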