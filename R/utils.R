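# Internal helpers: argument checking, seed substreams, step-function evaluation.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("hetsurv_invalid_argument", "hetsurv_error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("hetsurv_schema_error", "hetsurv_error")))
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x) || x < min)
    stop_invalid(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

# Deterministic substream seeds: independent streams (covariates, event
# uniforms, censoring uniforms, heterogeneity noise, bootstrap, scenarios)
# derived from one master seed, so e.g. adding censoring never perturbs the
# event times drawn under the same master seed. Plain multiplicative hash
# folded into the 31-bit range accepted by set.seed().
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- (as.double(seed) %% 2147483647) * 2654435761 + as.double(stream) * 97531
  as.integer(h %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Right-continuous step function defined by jump times and values, value
# `init` before the first jump. left = TRUE evaluates the left limit f(t-).
eval_step <- function(time, value, t, init = 1, left = FALSE) {
  idx <- findInterval(t, time, left.open = left)
  c(init, value)[idx + 1L]
}
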