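#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# clip to the camera's representable range
clip_intensity <- function(x, bit_depth) {
  pmin(pmax(x, 0), 2^bit_depth - 1)
}

# Deterministic per-unit seed derivation: a documented counter scheme.
# Child seed k of parent seed s is (s * 48271 + k) mod (2^31 - 1), kept
# strictly positive so it is always a valid 32-bit R seed.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k)
  as.integer(s %% 2147483647) + 1L
}

# robust scale: median absolute deviation without the consistency constant
raw_mad <- function(x) stats::median(abs(x - stats::median(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fs <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_fs("'%s' must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}
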