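# Synthetic example-cohort generator. Emulates the scale and structure of a
# screening cohort used to validate a diabetes-risk model: ~15,000 adults,
# four positively correlated continuous predictors, a low event count over a
# 6-year horizon, uniform-entry random censoring plus an administrative cap.
# All distributional details are synthetic choices; no real data is bundled.

#' Configure the synthetic example cohort
#'
#' Parameters of a synthetic validation-style cohort with four correlated
#' continuous predictors (age, BMI, triglyceride, fasting glucose),
#' exponential event times under a proportional-hazards model, uniform-entry
#' random censoring and an administrative horizon. The baseline hazard is
#' not set directly: it is solved numerically so the expected number of
#' events matches `target_events`. Predictor moments, correlations and
#' hazard ratios are synthetic but chosen to be clinically plausible for a
#' middle-aged screening population.
#'
#' @param n_subjects Cohort size (default 15464).
#' @param target_events Expected number of events over follow-up (default
#'   192); must be below `n_subjects`.
#' @param admin_horizon Administrative censoring time in years (default 6).
#' @param predictor_means,predictor_sds Named numeric vectors for `age`,
#'   `bmi`, `triglyceride`, `glucose`.
#' @param correlation Common pairwise correlation among predictors in
#'   `[0, 1)` (default 0.3).
#' @param log_hrs Named log hazard ratios per predictor (per unit).
#' @param max_entry_delay Upper bound, in years, of the uniform staggered
#'   entry that produces random censoring before the horizon (default 3).
#' @param seed Master seed.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_subjects = 15464,
                           target_events = 192,
                           admin_horizon = 6,
                           predictor_means = c(age = 44, bmi = 22.1,
                                               triglyceride = 0.9, glucose = 5.2),
                           predictor_sds = c(age = 9, bmi = 3.1,
                                             triglyceride = 0.6, glucose = 0.6),
                           correlation = 0.3,
                           log_hrs = c(age = 0.04, bmi = 0.15,
                                       triglyceride = 0.3, glucose = 0.8),
                           max_entry_delay = 3,
                           seed = NULL) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  target_events <- check_count(target_events, "target_events")
  if (target_events >= n_subjects && target_events != n_subjects)
    stop_invalid("target_events must be at most n_subjects")
  check_scalar_number(admin_horizon, "admin_horizon", positive = TRUE)
  check_scalar_number(correlation, "correlation", nonneg = TRUE)
  if (correlation >= 1) stop_invalid("correlation must be < 1")
  nm <- c("age", "bmi", "triglyceride", "glucose")
  for (v in list(predictor_means, predictor_sds, log_hrs))
    if (!all(nm %in% names(v))) stop_invalid("predictor vectors must name ",
                                             paste(nm, collapse = ", "))
  structure(list(n_subjects = n_subjects, target_events = target_events,
                 admin_horizon = admin_horizon,
                 predictor_means = predictor_means[nm],
                 predictor_sds = predictor_sds[nm],
                 correlation = correlation, log_hrs = log_hrs[nm],
                 max_entry_delay = max_entry_delay, seed = seed),
            class = "fixture_config")
}

#' Generate the synthetic example cohort
#'
#' Draws correlated Gaussian predictors, solves the baseline hazard so the
#' expected event count (given the realized covariates and censoring times)
#' equals the configured target, then draws exponential event times and
#' applies censoring. Censoring time per subject is
#' `admin_horizon - entry_delay` with `entry_delay ~ U(0, max_entry_delay)`,
#' i.e. uniform staggered entry with a common administrative closing date.
#'
#' @param config A [fixture_config()].
#' @return A `cohort_table` data.frame with columns `subject_id`, the four
#'   predictors, `true_event_time`, `observed_time`, `event`.
#' @export
generate_example_cohort <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_subjects
  nm <- names(config$predictor_means)
  p <- length(nm)

  # correlated Gaussians via Cholesky of an equicorrelation matrix
  R <- matrix(config$correlation, p, p); diag(R) <- 1
  L <- chol(R)
  Zm <- matrix(draw_covariates(n * p, seed = derive_seed(config$seed, 1L)), n, p)
  X <- Zm %*% L
  X <- sweep(sweep(X, 2, config$predictor_sds, "*"), 2, config$predictor_means, "+")
  colnames(X) <- nm

  lp <- drop(X %*% config$log_hrs[nm])
  lp <- lp - mean(lp)  # work on a centred scale; absorbed into the solved baseline
  cens <- config$admin_horizon -
    with_seed(derive_seed(config$seed, 2L),
              runif(n, 0, config$max_entry_delay))
  cens <- pmax(cens, 1e-3)

  # expected events given covariates and censoring times, as a function of
  # the baseline hazard: sum_i 1 - exp(-lambda0 * exp(lp_i) * c_i)
  expected_events <- function(lambda0) sum(1 - exp(-lambda0 * exp(lp) * cens))
  if (config$target_events >= n) {
    lambda0 <- 1e6  # effectively immediate events
  } else {
    upper <- 1
    while (expected_events(upper) < config$target_events && upper < 1e8) upper <- upper * 10
    if (expected_events(upper) < config$target_events)
      stop(errorCondition("target event count unreachable for this configuration",
                          class = c("hetsurv_config_error", "hetsurv_error")))
    lambda0 <- uniroot(function(l) expected_events(l) - config$target_events,
                       c(1e-12, upper), tol = 1e-12)$root
  }

  tt <- sample_event_times(lp, baseline_hazard = lambda0, log_hr = 1,
                           seed = derive_seed(config$seed, 3L))
  out <- data.frame(subject_id = seq_len(n), X)
  out$true_event_time <- tt
  out$observed_time <- pmin(tt, cens)
  out$event <- as.integer(tt <= cens)
  attr(out, "baseline_hazard") <- lambda0
  class(out) <- c("cohort_table", "data.frame")
  out
}
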