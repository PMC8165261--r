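# Internal helpers shared across modules.

#' Round half away from zero ("round half up" for non-negative input)
#'
#' Base R `round()` rounds half to even; sample-count arithmetic here
#' follows the usual "0.5 rounds up" convention so that printed
#' proportion-to-count tables are reproduced exactly.
#'
#' @param x numeric vector, assumed non-negative.
#' @return integer vector.
#' @noRd
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Derive a child seed from a base seed and a counter
#'
#' Deterministic arithmetic derivation (no RNG draw), so that per-patient or
#' per-sample streams are stable under partial regeneration: changing how
#' many items are generated never shifts the seed of an existing item.
#' Result is kept inside the 32-bit signed integer range.
#'
#' @param seed integer base seed.
#' @param index non-negative integer counter.
#' @param stream optional sub-stream counter.
#' @noRd
derive_seed <- function(seed, index, stream = 0L) {
  m <- 2147483647
  s <- (as.double(seed) %% m + as.double(index) * 48271 +
          as.double(stream) * 1299709) %% m
  as.integer(s)
}

#' Stop unless a condition holds, with sprintf-style message
#' @noRd
stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Check that x is a single finite number
#' @noRd
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Check that x is a fraction within [lo, hi]
#' @noRd
check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is_scalar_number(x)) {
    stopf("`%s` must be a single finite number, got %s", name,
          paste(class(x), collapse = "/"))
  }
  lo_ok <- if (lo_open) x > lo else x >= lo
  hi_ok <- if (hi_open) x < hi else x <= hi
  if (!lo_ok || !hi_ok) {
    stopf("`%s` must lie in %s%g, %g%s, got %g", name,
          if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]", x)
  }
  invisible(x)
}
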