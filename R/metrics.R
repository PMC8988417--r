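# Horizon-specific performance battery: O/E ratio, cumulative-dynamic AUC,
# Brier score and IPA, with reverse-Kaplan-Meier (IPCW) censoring weights.

as_pred_vector <- function(predictions) {
  if (inherits(predictions, "prediction_set")) predictions$predicted_survival
  else as.numeric(predictions)
}

check_surv_inputs <- function(times, events) {
  if (length(times) == 0L) stop_invalid("empty input")
  if (length(times) != length(events)) stop_invalid("times and events must match in length")
  if (any(!events %in% c(0, 1))) stop_invalid("events must be 0/1")
  if (any(times <= 0)) stop_invalid("times must be positive")
  invisible(NULL)
}

# Product-limit curve as (time, surv) jump points over unique event times.
# Computed directly (sorted risk sets + cumulative product) rather than via
# survfit: the bootstrap loops evaluate it thousands of times and the
# formula-interface overhead dominates at that call rate. Verified against
# survival::survfit in the test suite.
km_curve <- function(times, events) {
  ord <- order(times)
  ts <- times[ord]; ev <- events[ord]
  idx_first <- which(!duplicated(ts))
  idx_last <- which(!duplicated(ts, fromLast = TRUE))
  at_risk <- length(ts) - idx_first + 1
  d <- diff(c(0, cumsum(ev)[idx_last]))
  surv <- cumprod(1 - d / at_risk)
  keep <- d > 0
  list(time = ts[idx_last][keep], surv = surv[keep])
}

#' Kaplan-Meier survival probability at a time point
#'
#' Product-limit estimate \eqn{S_{KM}(t)}; equal to 1 before the first event
#' and, under no censoring, to the empirical proportion with time exceeding
#' `t`.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param t Evaluation time (>= 0).
#' @return Survival probability in `[0, 1]`.
#' @export
km_survival <- function(times, events, t) {
  check_surv_inputs(times, events)
  check_scalar_number(t, "t", nonneg = TRUE)
  cv <- km_curve(times, events)
  eval_step(cv$time, cv$surv, t, init = 1)
}

#' Censoring survival probability (reverse Kaplan-Meier)
#'
#' Kaplan-Meier applied with the event indicator inverted, estimating the
#' probability \eqn{G(t)} of remaining uncensored beyond `t` — the weighting
#' function for inverse-probability-of-censoring-weighted metrics.
#'
#' @inheritParams km_survival
#' @param left If `TRUE`, return the left limit \eqn{G(t^-)}.
#' @return Censoring-free probability in `(0, 1]`.
#' @export
censoring_survival <- function(times, events, t, left = FALSE) {
  check_surv_inputs(times, events)
  cv <- km_curve(times, 1 - events)
  g <- eval_step(cv$time, cv$surv, t, init = 1, left = left)
  if (any(g <= 0))
    stop(errorCondition(
      "censoring survival G is 0 at an evaluation point; choose a smaller horizon",
      class = c("hetsurv_weighting_error", "hetsurv_error")))
  g
}

#' Observed/expected ratio at a horizon (calibration-in-the-large)
#'
#' Compares the Kaplan-Meier estimate of the marginal outcome at `t` with
#' the average model prediction at `t`. The default `"event"` form is the
#' ratio of observed to mean predicted event probabilities, so values below
#' 1 mean predicted risks are too high on average; `"survival"` gives the
#' ratio of observed to mean predicted survival.
#'
#' @param predictions A `prediction_set` or numeric vector of predicted
#'   survival probabilities at `t`.
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param t Horizon.
#' @param type `"event"` (default) or `"survival"`.
#' @return Positive ratio; 1 indicates mean calibration.
#' @export
oe_ratio <- function(predictions, times, events, t, type = c("event", "survival")) {
  type <- match.arg(type)
  pred <- as_pred_vector(predictions)
  check_surv_inputs(times, events)
  if (length(pred) != length(times)) stop_invalid("predictions must match cohort size")
  skm <- km_survival(times, events, t)
  mp <- mean(pred)
  if (type == "event") {
    if (1 - mp <= 0) stop_invalid("mean predicted risk is 0; O/E undefined")
    (1 - skm) / (1 - mp)
  } else {
    if (mp <= 0) stop_invalid("mean predicted survival is 0; O/E undefined")
    skm / mp
  }
}

#' Cumulative-dynamic time-dependent AUC with IPCW
#'
#' Probability that a subject with an event by `t` (case) carries a higher
#' risk marker than a subject still event-free beyond `t` (control),
#' estimated over all case-control pairs with
#' inverse-probability-of-censoring weights: a case observed at time
#' \eqn{T_i} is weighted \eqn{1/G(T_i^-)} and every control \eqn{1/G(t)},
#' where \eqn{G} is the reverse Kaplan-Meier censoring curve. Marker ties
#' count 1/2. Under no censoring this reduces exactly to the Mann-Whitney
#' AUC for the binary outcome "event by `t`".
#'
#' @param marker Risk marker (linear predictor, predicted risk, or any
#'   monotone transform of risk; higher = higher risk).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param t Horizon.
#' @return AUC in `[0, 1]`.
#' @export
cd_auc <- function(marker, times, events, t) {
  check_surv_inputs(times, events)
  if (length(marker) != length(times)) stop_invalid("marker must match cohort size")
  is_case <- times <= t & events == 1
  is_ctrl <- times > t
  if (!any(is_case) || !any(is_ctrl))
    stop(errorCondition("no cases or no controls at t; AUC undefined",
                        class = c("hetsurv_undefined_metric", "hetsurv_error")))
  w_case <- if (all(events == 1)) rep(1, sum(is_case))
            else 1 / censoring_survival(times, events, times[is_case], left = TRUE)
  sc <- sort(marker[is_ctrl])
  m <- marker[is_case]
  n_less <- findInterval(m, sc, left.open = TRUE)
  n_leq <- findInterval(m, sc)
  # control weight 1/G(t) is common to all pairs and cancels
  sum(w_case * (n_less + 0.5 * (n_leq - n_less))) / (sum(w_case) * length(sc))
}

#' IPCW Brier score at a horizon
#'
#' Censoring-weighted mean squared error between the event-free indicator at
#' `t` and the predicted survival: subjects with an event by `t` contribute
#' \eqn{(0 - S)^2 / G(T_i^-)}, subjects observed beyond `t` contribute
#' \eqn{(1 - S)^2 / G(t)}, subjects censored before `t` contribute 0; the
#' divisor is the full sample size. Without censoring this is the plain mean
#' squared error.
#'
#' @inheritParams oe_ratio
#' @return Brier score in `[0, 1]` (up to weighting).
#' @export
brier_score <- function(predictions, times, events, t) {
  pred <- as_pred_vector(predictions)
  check_surv_inputs(times, events)
  if (length(pred) != length(times)) stop_invalid("predictions must match cohort size")
  n <- length(times)
  is_case <- times <= t & events == 1
  is_ctrl <- times > t
  no_cens <- all(events == 1)
  contrib <- numeric(n)
  if (any(is_case)) {
    g_case <- if (no_cens) 1
              else censoring_survival(times, events, times[is_case], left = TRUE)
    contrib[is_case] <- (0 - pred[is_case])^2 / g_case
  }
  if (any(is_ctrl)) {
    g_t <- if (no_cens) 1 else censoring_survival(times, events, t)
    contrib[is_ctrl] <- (1 - pred[is_ctrl])^2 / g_t
  }
  sum(contrib) / n
}

#' Index of prediction accuracy at a horizon
#'
#' Benchmarks the model's Brier score against a null model that predicts the
#' Kaplan-Meier marginal survival for every subject:
#' \eqn{IPA(t) = 1 - Brier_{model}(t) / Brier_{null}(t)}. 1 is a perfect
#' model, 0 an uninformative one, and negative values indicate a model
#' worse than using no patient information at all.
#'
#' @inheritParams oe_ratio
#' @return IPA, a real number at most 1.
#' @export
ipa <- function(predictions, times, events, t) {
  pred <- as_pred_vector(predictions)
  b_model <- brier_score(pred, times, events, t)
  b_null <- brier_score(rep(km_survival(times, events, t), length(times)),
                        times, events, t)
  if (b_null == 0)
    stop(errorCondition("null-model Brier score is 0; IPA undefined",
                        class = c("hetsurv_degenerate_outcome", "hetsurv_error")))
  1 - b_model / b_null
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects with replacement `B` times and recomputes a statistic
#' per resample; returns the percentile interval. Resamples where the
#' statistic is undefined are dropped, but if more than half fail the
#' bootstrap errors out.
#'
#' @param statistic Function taking an integer index vector (a resample of
#'   `seq_len(n)`) and returning a scalar.
#' @param n Number of subjects to resample.
#' @param B Number of bootstrap resamples (>= 2), default 500.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param seed Optional integer seed.
#' @return List with `lower`, `upper`, `level`, `B`, `n_failed`, and the
#'   vector of resample `values`.
#' @export
bootstrap_ci <- function(statistic, n, B = 500, level = 0.95, seed = NULL) {
  B <- check_count(B, "B", min = 2L)
  n <- check_count(n, "n")
  check_scalar_number(level, "level")
  if (level <= 0 || level >= 1) stop_invalid("level must be in (0, 1)")
  vals <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(as.numeric(statistic(idx)), hetsurv_error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(vals))
  if (n_failed > B / 2)
    stop(errorCondition(
      sprintf("statistic undefined in %d of %d bootstrap resamples", n_failed, B),
      class = c("hetsurv_bootstrap_error", "hetsurv_error")))
  qs <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
                 names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level, B = B,
       n_failed = n_failed, values = vals)
}

metric_names <- c("oe_ratio", "auc", "brier_model", "brier_null", "ipa")

# Point estimates of the full battery from raw vectors.
metrics_point <- function(pred, marker, times, events, t, oe_type = "event") {
  b_model <- brier_score(pred, times, events, t)
  b_null <- brier_score(rep(km_survival(times, events, t), length(times)),
                        times, events, t)
  c(oe_ratio = oe_ratio(pred, times, events, t, type = oe_type),
    auc = cd_auc(marker, times, events, t),
    brier_model = b_model,
    brier_null = b_null,
    ipa = 1 - b_model / b_null)
}

#' Validate a model on a cohort at a horizon
#'
#' Computes the full performance battery — O/E ratio, cumulative-dynamic
#' AUC, model and null Brier scores, and IPA — for a fitted or externally
#' supplied [model_spec()] on a cohort, optionally with percentile bootstrap
#' confidence intervals (subjects resampled as rows).
#'
#' @param model A [model_spec()].
#' @param cohort Data frame with the model predictors, follow-up time and
#'   event indicator.
#' @param horizon Evaluation horizon.
#' @param time,event Names of the follow-up-time and event columns.
#' @param oe_type `"event"` or `"survival"` form of the O/E ratio.
#' @param n_bootstrap Number of bootstrap resamples for CIs (0 = none).
#' @param level Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @param extrapolation Passed to [predict_survival()].
#' @return A `metrics_result` list: `horizon`, point estimates for each
#'   metric, optional `ci` (matrix with lower/upper rows), `n`,
#'   `n_bootstrap`.
#' @export
validate_model <- function(model, cohort, horizon, time = "observed_time",
                           event = "event", oe_type = c("event", "survival"),
                           n_bootstrap = 0, level = 0.95, seed = NULL,
                           extrapolation = c("fail", "clamp")) {
  oe_type <- match.arg(oe_type)
  if (!all(c(time, event) %in% names(cohort)))
    stop_schema("cohort is missing time/event columns")
  pred <- predict_survival(model, cohort, horizon,
                           extrapolation = extrapolation)$predicted_survival
  marker <- linear_predictor(model, cohort)
  times <- cohort[[time]]; events <- cohort[[event]]
  est <- metrics_point(pred, marker, times, events, horizon, oe_type)
  res <- list(horizon = horizon, estimates = est, ci = NULL,
              n = nrow(cohort), n_bootstrap = n_bootstrap, level = level)
  if (n_bootstrap > 0) {
    vals <- with_seed(seed, {
      t(vapply(seq_len(n_bootstrap), function(b) {
        idx <- sample.int(nrow(cohort), nrow(cohort), replace = TRUE)
        tryCatch(metrics_point(pred[idx], marker[idx], times[idx], events[idx],
                               horizon, oe_type),
                 hetsurv_error = function(e) setNames(rep(NA_real_, 5), metric_names))
      }, setNames(numeric(5), metric_names)))
    })
    n_failed <- sum(is.na(vals[, 1]))
    if (n_failed > n_bootstrap / 2)
      stop(errorCondition(
        sprintf("metrics undefined in %d of %d bootstrap resamples", n_failed, n_bootstrap),
        class = c("hetsurv_bootstrap_error", "hetsurv_error")))
    res$ci <- apply(vals, 2, quantile, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                    na.rm = TRUE)
    rownames(res$ci) <- c("lower", "upper")
  }
  class(res) <- "metrics_result"
  res
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("Performance at t = %g (n = %d)\n", x$horizon, x$n))
  for (m in metric_names) {
    line <- sprintf("  %-12s %8.4f", m, x$estimates[[m]])
    if (!is.null(x$ci))
      line <- paste0(line, sprintf("  [%.4f, %.4f]", x$ci["lower", m], x$ci["upper", m]))
    cat(line, "\n")
  }
  invisible(x)
}
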