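#' @keywords internal
"_PACKAGE"

# Abort helpers: all user-facing validation errors carry a class so callers
# (and tests) can distinguish bad input from internal failures.
abort_input <- function(msg, class = "urocomp_invalid_input") {
  stop(structure(
    class = c(class, "urocomp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort_input(sprintf(
      "`%s` must be %s %s (got %g)", name,
      if (strict) "greater than" else "at least", format(lower), x
    ))
  }
  invisible(x)
}

assert_increasing <- function(x, name) {
  if (length(x) == 0L) abort_input(sprintf("`%s` must be non-empty", name))
  if (any(!is.finite(x))) abort_input(sprintf("`%s` must be finite", name))
  if (length(x) > 1L && any(diff(x) <= 0)) {
    abort_input(sprintf("`%s` must be strictly increasing", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; a NULL seed leaves the global stream untouched.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Fixed-precision float serialization (9 significant digits) so that reports
# are byte-identical across reruns of the same config + seed.
signif9 <- function(x) {
  if (is.list(x)) return(lapply(x, signif9))
  if (is.double(x)) return(signif(x, 9L)) else x
}
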