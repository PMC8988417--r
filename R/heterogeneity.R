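#' Measurement-heterogeneity parameters
#'
#' A triple \eqn{(\psi, \theta, \sigma_\epsilon)} describing how a
#' predictor's measurement at implementation (\eqn{W}) relates to its
#' measurement at validation (\eqn{X}) under the linear measurement model
#' \eqn{W = \psi + \theta X + \epsilon}, \eqn{\epsilon \sim N(0,
#' \sigma_\epsilon^2)}. \eqn{\psi} is an additive systematic shift (same
#' units as the predictor), \eqn{\theta} a multiplicative systematic
#' association, and \eqn{\sigma_\epsilon} the standard deviation of extra
#' random measurement variation. \eqn{(0, 1, 0)} is measurement homogeneity.
#'
#' @param psi Additive shift.
#' @param theta Multiplicative association (> 0).
#' @param sigma_eps Standard deviation of the random deviation (>= 0).
#' @return An object of class `het_params`.
#' @export
het_params <- function(psi = 0, theta = 1, sigma_eps = 0) {
  check_scalar_number(psi, "psi")
  check_scalar_number(theta, "theta")
  check_scalar_number(sigma_eps, "sigma_eps")
  if (theta <= 0) stop_invalid("theta must be > 0")
  if (sigma_eps < 0) stop_invalid("sigma_eps must be >= 0")
  structure(list(psi = psi, theta = theta, sigma_eps = sigma_eps),
            class = "het_params")
}

is_homogeneity <- function(params) {
  params$psi == 0 && params$theta == 1 && params$sigma_eps == 0
}

#' Apply measurement heterogeneity to a predictor
#'
#' Transforms validation-setting measurements `x` into implementation-setting
#' measurements \eqn{w_i = \psi + \theta x_i + \epsilon_i} with
#' \eqn{\epsilon_i} iid \eqn{N(0, \sigma_\epsilon^2)}. The noise is drawn
#' fresh on every call from its own seeded substream.
#'
#' @param x Numeric vector of validation-setting measurements.
#' @param params A [het_params()] triple.
#' @param seed Optional integer seed for the noise draw.
#' @return Numeric vector `w` of the same length as `x`.
#' @export
apply_heterogeneity <- function(x, params, seed = NULL) {
  stopifnot(inherits(params, "het_params"))
  if (!is.numeric(x) || any(!is.finite(x))) stop_invalid("x must be finite numeric")
  eps <- if (params$sigma_eps > 0)
    with_seed(seed, rnorm(length(x), sd = params$sigma_eps)) else 0
  params$psi + params$theta * x + eps
}

#' Build a factorial grid of heterogeneity scenarios
#'
#' Full factorial grid of equally spaced levels (endpoints included) per
#' parameter, \eqn{levels^3} scenarios in total, ordered lexicographically
#' with \eqn{\psi} outermost, then \eqn{\theta}, then \eqn{\sigma_\epsilon}.
#' Three levels over the simulation-study ranges \eqn{\psi \in [-0.3, 0.3]},
#' \eqn{\theta \in [0.5, 2]}, \eqn{\sigma_\epsilon \in [0, \sqrt 2]} give the
#' 27-scenario design.
#'
#' @param psi_range,theta_range,sigma_range Length-2 numeric intervals
#'   `c(low, high)` with `low <= high`.
#' @param levels Number of equally spaced levels per parameter (>= 1; with
#'   one level the lower endpoint is used).
#' @return A `scenario_grid` data.frame with columns `label`, `psi`, `theta`,
#'   `sigma_eps`.
#' @export
scenario_grid <- function(psi_range = c(-0.3, 0.3),
                          theta_range = c(0.5, 2),
                          sigma_range = c(0, sqrt(2)),
                          levels = 3) {
  levels <- check_count(levels, "levels")
  lev <- function(r, name) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)))
      stop_invalid(name, " must be a finite numeric interval c(low, high)")
    if (r[1] > r[2]) stop_invalid(name, " is inverted: low > high")
    if (levels == 1L) r[1] else seq(r[1], r[2], length.out = levels)
  }
  psi <- lev(psi_range, "psi_range")
  theta <- lev(theta_range, "theta_range")
  if (any(theta <= 0)) stop_invalid("theta_range must be strictly positive")
  sigma <- lev(sigma_range, "sigma_range")
  if (any(sigma < 0)) stop_invalid("sigma_range must be non-negative")
  g <- expand.grid(sigma_eps = sigma, theta = theta, psi = psi,
                   KEEP.OUT.ATTRS = FALSE)[, c("psi", "theta", "sigma_eps")]
  as_scenario_grid(g)
}

#' Coerce a data.frame of (psi, theta, sigma_eps) rows to a scenario grid
#'
#' @param df A data.frame with numeric columns `psi`, `theta`, `sigma_eps`
#'   and optionally `label`.
#' @return A `scenario_grid` data.frame.
#' @export
as_scenario_grid <- function(df) {
  need <- c("psi", "theta", "sigma_eps")
  if (!all(need %in% names(df))) stop_schema("scenario grid needs columns psi, theta, sigma_eps")
  if (nrow(df) == 0L) stop_invalid("scenario grid must be non-empty")
  if (any(df$theta <= 0)) stop_invalid("theta must be > 0")
  if (any(df$sigma_eps < 0)) stop_invalid("sigma_eps must be >= 0")
  if (anyDuplicated(df[need])) stop_invalid("duplicate (psi, theta, sigma_eps) scenarios")
  if (is.null(df$label))
    df$label <- sprintf("psi=%g_theta=%g_sigma=%g", df$psi, df$theta, df$sigma_eps)
  df <- df[c("label", need)]
  rownames(df) <- NULL
  class(df) <- c("scenario_grid", "data.frame")
  df
}

grid_params <- function(grid, i) {
  het_params(grid$psi[i], grid$theta[i], grid$sigma_eps[i])
}
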