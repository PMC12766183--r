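#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed fan-out: every stochastic stage derives its own seed
# from the master seed and a small integer tag, so stages can be re-run (or
# parallelised) independently without sharing a global RNG stream.
# Exact in double arithmetic (product < 2^49) and always < 2^31.
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(as.numeric(master)) * 69069 + as.numeric(k) * 1013904223) %% 2147483629)
}

stop_field <- function(cond, field, msg) {
  if (!isTRUE(cond)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_proportion <- function(x, field, allow_one = TRUE) {
  stop_field(is.numeric(x) && length(x) == 1L && is.finite(x), field, "must be a single finite number")
  hi <- if (allow_one) x <= 1 else x < 1
  stop_field(x >= 0 && hi, field, sprintf("must lie in [0,%s]", if (allow_one) "1" else "1)"))
  x
}

check_range_pair <- function(x, field) {
  stop_field(is.numeric(x) && length(x) == 2L && all(is.finite(x)), field, "must be two finite numbers")
  stop_field(all(x >= 0) && all(x <= 1) && x[1] <= x[2], field, "must be an increasing pair in [0,1]")
  x
}

# Wald summary for one coefficient of a coxph fit
wald_row <- function(fit, term) {
  b <- stats::coef(fit)[[term]]
  se <- sqrt(diag(stats::vcov(fit))[[term]])
  z <- b / se
  list(
    estimate = b, se = se,
    hr = exp(b), ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
    p = 2 * stats::pnorm(-abs(z))
  )
}
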