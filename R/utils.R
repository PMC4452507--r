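#' Logistic (sigmoid) function with overflow guard
#'
#' Dot products are clipped to +/- 30 before exponentiation; at that point
#' the sigmoid is within 1e-13 of its limit, so the clip changes nothing at
#' the scales the model operates on while keeping the arithmetic finite.
#'
#' @param x numeric vector of linear scores.
#' @return numeric vector strictly inside (0, 1).
#' @keywords internal
sigmoid <- function(x) {
  x <- pmin(pmax(x, -30), 30)
  1 / (1 + exp(-x))
}

#' Derive a stream-specific seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range expected by
#' `set.seed()`.
#'
#' @param seed base integer seed.
#' @param offset non-negative integer identifying the consumer stream.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(offset)) %% 2147483647)
}

# stopifnot-style scalar checks with readable messages
check_scalar <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive (got %g)", name, x), call. = FALSE)
  }
  if (non_negative && x < 0) {
    stop(sprintf("`%s` must be non-negative (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
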