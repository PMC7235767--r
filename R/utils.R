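# Internal helpers shared across modules.

# R's round() is round-half-even; printed values in digester reports are
# conventionally round-half-up, so reported quantities go through this.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Truncation (not rounding) to `digits` decimals, e.g. 46.666... -> 46.66.
trunc_digits <- function(x, digits = 2) {
  p <- 10^digits
  trunc(x * p) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "digestor_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          "digestor_domain_error")
  }
  ok_low <- if (allow_zero_lower) x >= lower else x > lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper),
          "digestor_domain_error")
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
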