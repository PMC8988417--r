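test_that("Kaplan-Meier and reverse Kaplan-Meier match hand calculations", {
  # events at 1 and 3, censoring at 2; S(2.5) = (1 - 1/3) = 2/3
  expect_equal(km_survival(c(1, 2, 3), c(1, 0, 1), 2.5), 2 / 3)
  # reverse: censoring event at 2 among 2 at risk -> G(2.5) = 1/2
  expect_equal(censoring_survival(c(1, 2, 3), c(1, 0, 1), 2.5), 1 / 2)

  # swapping the indicator swaps the two estimators
  tms <- c(0.5, 1.2, 2.5, 3, 4.4); evs <- c(1, 0, 1, 0, 1)
  for (t in c(1, 2, 3.5)) {
    expect_equal(km_survival(tms, 1 - evs, t), censoring_survival(tms, evs, t))
    expect_equal(censoring_survival(tms, 1 - evs, t), km_survival(tms, evs, t))
  }

  # without censoring KM is the empirical survival proportion
  tt <- rexp(500) + 0.01
  expect_equal(km_survival(tt, rep(1, 500), 1), mean(tt > 1))

  expect_error(km_survival(numeric(0), numeric(0), 1),
               class = "hetsurv_invalid_argument")
})

test_that("the product-limit curve matches survival::survfit on censored data", {
  for (seed in c(4, 12)) {
    ch <- make_small_cohort(250, seed = seed)
    sf <- survival::survfit(survival::Surv(observed_time, event) ~ 1, data = ch)
    for (t in c(0.5, 2, 5, 9, 30)) {
      ref <- summary(sf, times = t, extend = TRUE)$surv
      expect_equal(km_survival(ch$observed_time, ch$event, t), ref,
                   tolerance = 1e-12)
    }
  }
})

test_that("O/E ratio detects the direction of mean miscalibration", {
  ch <- make_small_cohort(400, seed = 3)
  km_risk <- 1 - km_survival(ch$observed_time, ch$event, 5)
  # predictions equal to the KM-implied risk give exactly 1
  expect_equal(oe_ratio(rep(1 - km_risk, 400), ch$observed_time, ch$event, 5), 1)
  # overstated risks push O/E below 1; understated above
  expect_lt(oe_ratio(rep(1 - 2 * km_risk, 400), ch$observed_time, ch$event, 5), 1)
  expect_gt(oe_ratio(rep(1 - 0.5 * km_risk, 400), ch$observed_time, ch$event, 5), 1)
  # survival-ratio form is the flag-selectable alternative
  expect_equal(oe_ratio(rep(1 - km_risk, 400), ch$observed_time, ch$event, 5,
                        type = "survival"), 1)
})

test_that("IPCW cd-AUC and Brier match the brute-force oracles on censored cohorts", {
  for (seed in 1:3) {
    ch <- make_small_cohort(n = 150, seed = seed)
    marker <- 0.7 * ch$x
    pred <- exp(-0.1 * 5 * 2^ch$x)
    expect_equal(cd_auc(marker, ch$observed_time, ch$event, 5),
                 oracle_cd_auc(marker, ch$observed_time, ch$event, 5),
                 tolerance = 1e-12)
    expect_equal(brier_score(pred, ch$observed_time, ch$event, 5),
                 oracle_brier(pred, ch$observed_time, ch$event, 5),
                 tolerance = 1e-12)
  }
})

test_that("marker ties contribute half a concordant pair", {
  tms <- c(1, 2, 6, 7); evs <- c(1, 1, 1, 1)
  mk <- c(2, 1, 2, 1)  # each case ties one control, beats/loses the other
  expect_equal(cd_auc(mk, tms, evs, 5),
               oracle_cd_auc(mk, tms, evs, 5), tolerance = 1e-12)
  expect_equal(cd_auc(mk, tms, evs, 5), 0.5)
})

test_that("without censoring the metrics reduce to their binary analogues", {
  set.seed(7)
  n <- 2000
  x <- rnorm(n)
  tt <- sample_event_times(x, 0.1, log(2), seed = 8)
  ev <- rep(1L, n)
  pred <- exp(-0.65 * 2^x)
  y <- as.numeric(tt > 6.5)

  # Brier = plain MSE
  expect_equal(brier_score(pred, tt, ev, 6.5), mean((y - pred)^2))

  # cd-AUC = Mann-Whitney statistic of the binary outcome "event by t"
  marker <- x
  cases <- marker[y == 0]; ctrls <- marker[y == 1]
  mw <- mean(outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(cd_auc(marker, tt, ev, 6.5), mw)

  # uninformative marker sits at 1/2
  noise <- rnorm(1e5)
  tt2 <- rexp(1e5) + 0.01
  expect_equal(cd_auc(noise, tt2, rep(1L, 1e5), 1), 0.5, tolerance = 0.01)
})

test_that("IPA is zero for the null model, negative for a harmful one, and an exact identity", {
  ch <- make_small_cohort(500, seed = 9)
  t0 <- 5
  km <- km_survival(ch$observed_time, ch$event, t0)
  expect_equal(ipa(rep(km, 500), ch$observed_time, ch$event, t0), 0)

  # oracle predictions without censoring are perfect
  tt <- rexp(300) + 0.01
  expect_equal(brier_score(as.numeric(tt > 1), tt, rep(1L, 300), 1), 0)
  expect_equal(ipa(as.numeric(tt > 1), tt, rep(1L, 300), 1), 1)

  # sign-flipped model is worse than no information
  good <- exp(-0.1 * t0 * 2^ch$x)
  bad <- exp(-0.1 * t0 * 2^(-ch$x))
  expect_gt(ipa(good, ch$observed_time, ch$event, t0), 0)
  expect_lt(ipa(bad, ch$observed_time, ch$event, t0), 0)

  # bundle identity ipa = 1 - brier_model / brier_null holds exactly
  m <- model_spec(c(x = log(2)), list(kind = "exponential_rate", rate = 0.1))
  res <- validate_model(m, ch, t0)
  expect_identical(res$estimates[["ipa"]],
                   1 - res$estimates[["brier_model"]] / res$estimates[["brier_null"]])
})

test_that("cd-AUC is invariant to strictly increasing marker transforms", {
  ch <- make_small_cohort(300, seed = 10)
  a <- cd_auc(ch$x, ch$observed_time, ch$event, 5)
  expect_equal(cd_auc(0.4 + 1.9 * ch$x, ch$observed_time, ch$event, 5), a)
  expect_equal(cd_auc(exp(ch$x), ch$observed_time, ch$event, 5), a)
})

test_that("undefined-metric and weighting guards fire", {
  expect_error(cd_auc(1:4, c(1, 2, 3, 4), rep(1L, 4), 10),
               class = "hetsurv_undefined_metric")
  expect_error(cd_auc(1:4, c(6, 7, 8, 9), rep(0L, 4), 5),
               class = "hetsurv_undefined_metric")
  # everyone censored by t: G(t) hits zero
  expect_error(censoring_survival(c(1, 2, 3), c(0, 0, 0), 5),
               class = "hetsurv_weighting_error")
})

test_that("percentile bootstrap is deterministic, degenerate-safe and calibrated", {
  stat_const <- function(idx) 1
  ci <- bootstrap_ci(stat_const, n = 50, B = 100, seed = 1)
  expect_equal(ci$lower, 1); expect_equal(ci$upper, 1)

  x <- rnorm(200)
  stat_mean <- function(idx) mean(x[idx])
  c1 <- bootstrap_ci(stat_mean, n = 200, B = 200, seed = 2)
  c2 <- bootstrap_ci(stat_mean, n = 200, B = 200, seed = 2)
  expect_identical(c1[c("lower", "upper")], c2[c("lower", "upper")])

  # coverage of the true mean 0 for N(0,1) samples, 200 outer replicates
  set.seed(3)
  cover <- vapply(1:200, function(r) {
    y <- rnorm(200)
    ci <- bootstrap_ci(function(idx) mean(y[idx]), n = 200, B = 500,
                       seed = 1000 + r)
    ci$lower <= 0 && 0 <= ci$upper
  }, logical(1))
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)

  # a mostly-undefined statistic is an error, not a quiet interval
  stat_bad <- function(idx) stop(errorCondition("no", class = "hetsurv_error"))
  expect_error(bootstrap_ci(stat_bad, n = 20, B = 10, seed = 4),
               class = "hetsurv_bootstrap_error")
})
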