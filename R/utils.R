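# shared internal helpers

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# One sub-seed per Monte-Carlo repetition, derived deterministically from the
# root seed, so rep r's draws do not depend on how many draws earlier reps
# consumed (results are stable under reordering or chunked execution).
rep_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

# Probability-weight (normalized) mean and population SD.
weighted_moments <- function(values, weights) {
  w <- weights / sum(weights)
  m <- sum(w * values)
  list(mean = m, sd = sqrt(sum(w * (values - m)^2)), weights = w)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) & (allow_inf | is.finite(x)) & x >= lower & x <= upper
  if (!all(ok)) {
    abort(sprintf("`%s` must be numeric in [%s, %s]; got invalid value(s): %s",
                  name, format(lower), format(upper),
                  paste(utils::head(format(x[!ok]), 5), collapse = ", ")),
          class = "standcompare_domain_error")
  }
  invisible(x)
}
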