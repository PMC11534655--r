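# Internal validation helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Assert that `x` is a single finite number, optionally within (lower, upper).
# `name` appears in the error so callers can report the offending field.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_lower <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_lower || x > upper) {
    stop(sprintf("`%s` = %g is outside the allowed range [%g, %g]",
                 name, x, lower, upper), call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

# Run `expr` with a fixed RNG seed, leaving the caller's RNG state untouched.
with_fixed_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), expr)
}
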