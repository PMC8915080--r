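# Internal numeric helpers shared across modules.

#' @importFrom stats approx median rnorm runif sd spline
#' @importFrom utils read.table write.table head tail
NULL

# Numerically stable softmax of a vector.
softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Row-wise stable softmax of a matrix.
softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  z <- exp(m - mx)
  z / rowSums(z)
}

# Run `expr` under a temporary RNG seed when `seed` is non-NULL, leaving the
# caller's RNG stream untouched; with seed = NULL the global stream is used.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
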