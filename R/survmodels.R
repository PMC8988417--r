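#' Construct a proportional-hazards prediction model specification
#'
#' A `model_spec` represents an existing prediction model independently of
#' how it was obtained: named log-hazard-ratio coefficients, a baseline
#' survival (either a constant-hazard rate or a right-continuous step
#' function), and per-predictor centering offsets. Predicted survival is
#' \eqn{S(t \mid x) = S_0(t)^{\exp(LP)}} with
#' \eqn{LP = \sum_j \beta_j (x_j - c_j)}. Published models can be represented
#' directly, without refitting, by passing their coefficients and baseline.
#'
#' @param coefficients Named numeric vector of log hazard ratios.
#' @param baseline Either `list(kind = "exponential_rate", rate = lambda0)`
#'   or `list(kind = "step_function", time = ..., surv = ...)` with `surv`
#'   non-increasing in `(0, 1]` and implicitly 1 before the first time.
#' @param centering Named numeric vector of centering offsets; default all
#'   zero (uncentered, the common situation in clinical practice).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(coefficients, baseline, centering = NULL) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop_invalid("coefficients must be a named vector")
  if (any(!is.finite(coefficients))) stop_invalid("coefficients must be finite")
  if (is.null(centering)) centering <- setNames(rep(0, length(coefficients)),
                                                names(coefficients))
  if (!all(names(coefficients) %in% names(centering)))
    stop_invalid("centering must cover all coefficient names")
  kind <- baseline$kind
  if (identical(kind, "exponential_rate")) {
    check_scalar_number(baseline$rate, "baseline rate", positive = TRUE)
  } else if (identical(kind, "step_function")) {
    tm <- baseline$time; sv <- baseline$surv
    if (length(tm) != length(sv) || length(tm) == 0L)
      stop_invalid("step baseline needs equal-length time and surv")
    if (is.unsorted(tm, strictly = FALSE)) stop_invalid("baseline times must be sorted")
    if (any(sv < 0 | sv > 1) || any(diff(sv) > 1e-12))
      stop_invalid("baseline survival must be non-increasing within [0, 1]")
  } else stop_invalid("baseline$kind must be 'exponential_rate' or 'step_function'")
  structure(list(coefficients = coefficients, baseline = baseline,
                 centering = centering[names(coefficients)]),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Proportional-hazards model spec\n")
  cat("  coefficients:",
      paste(sprintf("%s=%.4f", names(x$coefficients), x$coefficients), collapse = ", "),
      "\n")
  if (x$baseline$kind == "exponential_rate")
    cat(sprintf("  baseline: exponential, rate %.6g\n", x$baseline$rate))
  else
    cat(sprintf("  baseline: step function, %d steps to t = %.4g\n",
                length(x$baseline$time), max(x$baseline$time)))
  if (any(x$centering != 0))
    cat("  centering:", paste(sprintf("%s=%.4f", names(x$centering), x$centering),
                              collapse = ", "), "\n")
  invisible(x)
}

check_cohort_fit_inputs <- function(cohort, predictors, time, event) {
  miss <- setdiff(c(predictors, time, event), names(cohort))
  if (length(miss)) stop_schema("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (any(!cohort[[event]] %in% c(0, 1))) stop_schema("event column must be 0/1")
  if (sum(cohort[[event]]) < 2) stop_invalid("need at least 2 events to fit")
  invisible(NULL)
}

#' Fit a parametric exponential proportional-hazards model
#'
#' Maximum-likelihood fit of the hazard \eqn{\lambda_0 \exp(\beta' x)} under
#' right censoring. The likelihood is identical to that of a Poisson
#' regression of the event indicator with the log follow-up time as offset,
#' which is how the MLE is computed.
#'
#' @param cohort Data frame with follow-up time, event indicator and
#'   predictors.
#' @param predictors Character vector of predictor column names.
#' @param time,event Names of the follow-up-time and event columns.
#' @param center If `TRUE`, centre the linear predictor at the fitting data's
#'   predictor means (stored as centering offsets, with the baseline adjusted
#'   accordingly). Default `FALSE`: centring is uncommon in deployed clinical
#'   models and damps the apparent impact of measurement shifts.
#' @return A [model_spec()] with an exponential-rate baseline.
#' @export
fit_exponential_ph <- function(cohort, predictors, time = "observed_time",
                               event = "event", center = FALSE) {
  check_cohort_fit_inputs(cohort, predictors, time, event)
  dat <- cohort[, c(predictors, time, event), drop = FALSE]
  names(dat) <- c(predictors, ".time", ".event")
  f <- as.formula(paste(".event ~", paste(predictors, collapse = " + ")))
  fit <- glm(f, family = poisson(), data = dat, offset = log(dat$.time))
  cf <- coef(fit)
  if (any(is.na(cf)) || !fit$converged)
    stop(errorCondition(
      paste("exponential fit failed:",
            if (any(is.na(cf))) "singular design (constant predictor?)" else "no convergence"),
      class = c("hetsurv_fit_error", "hetsurv_error")))
  beta <- cf[predictors]
  rate <- unname(exp(cf[1]))
  ctr <- setNames(rep(0, length(predictors)), predictors)
  if (center) {
    ctr <- colMeans(dat[, predictors, drop = FALSE])
    rate <- rate * exp(sum(beta * ctr))
  }
  model_spec(coefficients = beta,
             baseline = list(kind = "exponential_rate", rate = rate),
             centering = ctr)
}

#' Fit a Cox proportional-hazards model with Breslow baseline
#'
#' Semi-parametric partial-likelihood fit (Efron tie handling) via
#' [survival::coxph()], with the baseline survival extracted as an
#' uncentered step function from the Breslow cumulative-hazard estimator.
#'
#' @inheritParams fit_exponential_ph
#' @return A [model_spec()] with a step-function baseline.
#' @export
fit_cox <- function(cohort, predictors, time = "observed_time", event = "event",
                    center = FALSE) {
  check_cohort_fit_inputs(cohort, predictors, time, event)
  dat <- cohort[, c(predictors, time, event), drop = FALSE]
  f <- as.formula(paste0("Surv(", time, ", ", event, ") ~ ",
                         paste(predictors, collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(f, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("singular|infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop(errorCondition(paste("Cox fit failed:", conditionMessage(w)),
                            class = c("hetsurv_fit_error", "hetsurv_error")))
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop(errorCondition("Cox fit failed: singular design (constant predictor?)",
                        class = c("hetsurv_fit_error", "hetsurv_error")))
  bh <- basehaz(fit, centered = center)
  ctr <- if (center) colMeans(dat[, predictors, drop = FALSE])
         else setNames(rep(0, length(predictors)), predictors)
  model_spec(coefficients = cf[predictors],
             baseline = list(kind = "step_function",
                             time = bh$time, surv = exp(-bh$hazard)),
             centering = ctr)
}

baseline_survival_at <- function(model, horizon, extrapolation = c("fail", "clamp")) {
  extrapolation <- match.arg(extrapolation)
  if (model$baseline$kind == "exponential_rate")
    return(exp(-model$baseline$rate * horizon))
  tm <- model$baseline$time
  if (horizon > max(tm)) {
    if (extrapolation == "fail")
      stop(errorCondition(
        sprintf("horizon %.4g beyond last baseline step %.4g; use extrapolation = 'clamp' to carry the last value forward", horizon, max(tm)),
        class = c("hetsurv_extrapolation_error", "hetsurv_error")))
    horizon <- max(tm)
  }
  eval_step(tm, model$baseline$surv, horizon, init = 1)
}

#' Linear predictor of a model on new data
#'
#' @param model A [model_spec()].
#' @param newdata Data frame containing all model predictors.
#' @return Numeric vector \eqn{\sum_j \beta_j (x_j - c_j)} per row.
#' @export
linear_predictor <- function(model, newdata) {
  stopifnot(inherits(model, "model_spec"))
  nm <- names(model$coefficients)
  miss <- setdiff(nm, names(newdata))
  if (length(miss)) stop_schema("newdata is missing predictors: ",
                                paste(miss, collapse = ", "))
  X <- as.matrix(newdata[nm])
  drop(sweep(X, 2, model$centering[nm]) %*% model$coefficients)
}

#' Predict survival at a horizon
#'
#' Evaluates \eqn{S(t \mid x) = S_0(t)^{\exp(LP)}} for every row of
#' `newdata`.
#'
#' @param model A [model_spec()].
#' @param newdata Data frame of predictor values (optionally a
#'   `subject_id` column, otherwise row numbers are used).
#' @param horizon Prediction horizon (> 0); must lie within the baseline's
#'   support unless `extrapolation = "clamp"`.
#' @param extrapolation `"fail"` (default) errors when the horizon exceeds
#'   the last baseline step; `"clamp"` carries the last value forward.
#' @return A `prediction_set` data.frame with columns `subject_id` and
#'   `predicted_survival`, and the horizon as an attribute.
#' @export
predict_survival <- function(model, newdata, horizon,
                             extrapolation = c("fail", "clamp")) {
  check_scalar_number(horizon, "horizon", positive = TRUE)
  s0 <- baseline_survival_at(model, horizon, extrapolation)
  lp <- linear_predictor(model, newdata)
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(newdata)) newdata$subject_id
                 else seq_len(nrow(newdata)),
    predicted_survival = s0^exp(lp))
  attr(out, "horizon") <- horizon
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Recalibrate a model's baseline survival with a linear-predictor offset
#'
#' Re-estimates the baseline survival from a cohort while keeping the
#' coefficients fixed: each subject's linear predictor enters a Cox model as
#' an offset, and the Breslow baseline of that offset-only fit replaces the
#' original baseline. This updates calibration-in-the-large without touching
#' the model's discrimination.
#'
#' @param model A [model_spec()].
#' @param cohort Data frame with the model predictors, follow-up time and
#'   event indicator.
#' @param time,event Names of the follow-up-time and event columns.
#' @return A [model_spec()] with the same coefficients and a step-function
#'   baseline estimated from `cohort`.
#' @export
recalibrate_baseline <- function(model, cohort, time = "observed_time",
                                 event = "event") {
  stopifnot(inherits(model, "model_spec"))
  if (!all(c(time, event) %in% names(cohort)))
    stop_schema("cohort is missing time/event columns")
  if (sum(cohort[[event]]) < 1)
    stop_invalid("cohort has no events; cannot recalibrate")
  lp <- linear_predictor(model, cohort)
  bl <- breslow_baseline(cohort[[time]], cohort[[event]], lp)
  model_spec(coefficients = model$coefficients,
             baseline = list(kind = "step_function",
                             time = bl$time, surv = bl$surv),
             centering = model$centering)
}

# Breslow cumulative-hazard baseline with the linear predictor as a fixed
# offset: H0(t) = sum over event times s <= t of d(s) / sum_{at risk} exp(lp).
# Computed directly because survfit/basehaz reference offset models at the
# mean offset, not at offset zero.
breslow_baseline <- function(times, events, lp) {
  ord <- order(times)
  ts <- times[ord]; ev <- events[ord]; w <- exp(lp[ord])
  at_risk <- rev(cumsum(rev(w)))
  first <- !duplicated(ts)
  # risk set evaluated at the start of each tied-time group
  ar <- at_risk[first][cumsum(first)]
  H <- cumsum(ev / ar)
  idx_last <- which(!duplicated(ts, fromLast = TRUE))
  d <- diff(c(0, cumsum(ev)[idx_last]))
  list(time = ts[idx_last][d > 0], surv = exp(-H[idx_last][d > 0]))
}
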