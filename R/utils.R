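#' @keywords internal
"_PACKAGE"

# Argument checks -------------------------------------------------------

stop_invalid <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    stop_invalid("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stop_invalid("`%s` must be >= %g", name, lower)
  if (x > upper)
    stop_invalid("`%s` must be <= %g", name, upper)
  invisible(x)
}

#' Evaluate an expression with a local, restorable RNG state
#'
#' All generators in the package are pure functions of their seed: the
#' global RNG stream of the caller is left untouched.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("`seed` must be a single finite number")
  withr::with_seed(as.integer(seed), expr)
}

# z-score a vector; zero-variance input is an error unless `allow_constant`
zscore <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(x - mean(x))
    stop_invalid("cannot z-score a zero-variance signal")
  }
  (x - mean(x)) / s
}

# next power of two at or above n (FFT convolution sizing)
next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))
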