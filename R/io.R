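# Delimited-text cohort I/O with schema validation, and structured
# (YAML) serialization for model specs, scenario grids and configs.
# Dialect: comma separator, "." decimal, UTF-8, header row, no index column.

#' Read and validate a cohort CSV
#'
#' Requires columns `subject_id`, `observed_time` and `event` (extra columns
#' are preserved). Validates before anything downstream runs: numeric cells,
#' positive times, 0/1 events, no missing values; violations raise a schema
#' error naming the offending row and column.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `cohort_table` data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_schema("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df, where = path)
}

#' Validate a data.frame as a cohort table
#'
#' @param df Data frame to validate.
#' @param where Label used in error messages.
#' @return `df` with class `cohort_table`, invisibly unchanged otherwise.
#' @export
validate_cohort <- function(df, where = "cohort") {
  need <- c("subject_id", "observed_time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_schema(where, ": missing required columns: ", paste(miss, collapse = ", "))
  for (col in c("observed_time", "event")) {
    v <- df[[col]]
    if (!is.numeric(v)) stop_schema(where, ": column '", col, "' is not numeric")
    if (anyNA(v))
      stop_schema(where, ": missing value in column '", col, "', row ",
                  which(is.na(v))[1])
  }
  bad <- which(df$observed_time <= 0)
  if (length(bad))
    stop_schema(where, ": non-positive observed_time in row ", bad[1])
  bad <- which(!df$event %in% c(0, 1))
  if (length(bad))
    stop_schema(where, ": event not in {0, 1} in row ", bad[1],
                " (value ", df$event[bad[1]], ")")
  if ("true_event_time" %in% names(df)) {
    bad <- which(df$observed_time > df$true_event_time + 1e-8)
    if (length(bad))
      stop_schema(where, ": observed_time exceeds true_event_time in row ", bad[1])
  }
  if (!inherits(df, "cohort_table")) class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize a model specification
#'
#' Model specs are stored as YAML: predictor names, coefficients, centering
#' offsets and the baseline as either `{kind: exponential_rate, rate: ...}`
#' or `{kind: step_function, time: [...], surv: [...]}`.
#'
#' @param model A [model_spec()].
#' @param path File path.
#' @return `read_model_spec()` returns a [model_spec()];
#'   `write_model_spec()` returns `path` invisibly.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "model_spec"))
  obj <- list(predictors = names(model$coefficients),
              coefficients = as.list(model$coefficients),
              centering = as.list(model$centering),
              baseline = model$baseline)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop_schema("model file not found: ", path)
  obj <- yaml::read_yaml(path)
  cf <- unlist(obj$coefficients)[obj$predictors]
  ctr <- if (!is.null(obj$centering)) unlist(obj$centering)[obj$predictors] else NULL
  bl <- obj$baseline
  if (identical(bl$kind, "step_function")) {
    bl$time <- as.numeric(bl$time); bl$surv <- as.numeric(bl$surv)
  }
  model_spec(coefficients = cf, baseline = bl, centering = ctr)
}

#' Serialize / deserialize a scenario grid
#'
#' Grids are stored as CSV with columns `label`, `psi`, `theta`,
#' `sigma_eps`.
#'
#' @param grid A [scenario_grid()].
#' @param path File path.
#' @return `read_scenario_grid()` returns a `scenario_grid`;
#'   `write_scenario_grid()` returns `path` invisibly.
#' @export
write_scenario_grid <- function(grid, path) {
  stopifnot(inherits(grid, "scenario_grid"))
  write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenario_grid
#' @export
read_scenario_grid <- function(path) {
  if (!file.exists(path)) stop_schema("scenario grid file not found: ", path)
  as_scenario_grid(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a structured configuration file
#'
#' Reads a YAML file whose keys mirror the fields of [dgm_config()],
#' [qpea_config()] or [fixture_config()]; used by the command-line
#' interface.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_schema("config file not found: ", path)
  yaml::read_yaml(path)
}
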