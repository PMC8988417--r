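# Independent brute-force oracles for the IPCW metrics, kept deliberately
# naive (explicit double loops, explicit weights) so they share no code with
# the package implementations.

oracle_reverse_km <- function(times, events, t, left = FALSE) {
  # product-limit over censoring events, evaluated at t (or its left limit)
  ord <- order(times)
  ts <- times[ord]; cs <- 1 - events[ord]
  g <- 1
  for (u in unique(ts)) {
    if (if (left) u >= t else u > t) break
    n_risk <- sum(ts >= u)
    d <- sum(cs[ts == u])
    g <- g * (1 - d / n_risk)
  }
  g
}

oracle_cd_auc <- function(marker, times, events, t) {
  cases <- which(times <= t & events == 1)
  ctrls <- which(times > t)
  g_t <- oracle_reverse_km(times, events, t)
  num <- 0; den <- 0
  for (i in cases) {
    wi <- 1 / oracle_reverse_km(times, events, times[i], left = TRUE)
    for (j in ctrls) {
      wj <- 1 / g_t
      conc <- if (marker[i] > marker[j]) 1 else if (marker[i] == marker[j]) 0.5 else 0
      num <- num + wi * wj * conc
      den <- den + wi * wj
    }
  }
  num / den
}

oracle_brier <- function(pred, times, events, t) {
  n <- length(times)
  total <- 0
  for (i in seq_len(n)) {
    if (times[i] <= t && events[i] == 1) {
      total <- total + (0 - pred[i])^2 / oracle_reverse_km(times, events, times[i], left = TRUE)
    } else if (times[i] > t) {
      total <- total + (1 - pred[i])^2 / oracle_reverse_km(times, events, t)
    }
  }
  total / n
}

# small censored cohort with a prognostic marker, for oracle comparisons
make_small_cohort <- function(n = 150, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  tt <- -log(runif(n)) / (0.1 * 2^x)
  cc <- -log(runif(n)) / 0.08
  data.frame(x = x,
             observed_time = pmin(tt, cc),
             event = as.integer(tt <= cc))
}

table1_config <- function(n, censoring = "none", seed = 1) {
  dgm_config(n = n, baseline_hazard = 0.1, log_hr = log(2),
             censoring = censoring, admin_time = 15,
             censor_baseline_hazard = 0.01, censor_log_hr = log(3),
             seed = seed)
}
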