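make_qpea_setup <- function(n = 4000, seed = 81) {
  ch <- generate_cohort(table1_config(n, "administrative", seed = seed))
  model <- fit_cox(ch, "x")
  list(cohort = ch, model = model)
}

test_that("the homogeneity scenario reproduces plain validation exactly and leaves the model untouched", {
  s <- make_qpea_setup()
  grid <- as_scenario_grid(data.frame(psi = 0, theta = 1, sigma_eps = 0))
  cfg <- qpea_config("x", grid, horizon = 6.5, n_bootstrap = 0, seed = 2)
  coef_before <- c(s$model$coefficients)
  surv_before <- c(s$model$baseline$surv)
  rep <- run_scenarios(s$cohort, s$model, cfg)
  expect_identical(c(s$model$coefficients), coef_before)
  expect_identical(c(s$model$baseline$surv), surv_before)

  ref <- rep$reference$estimates
  for (m in c("oe_ratio", "auc", "brier_model", "brier_null", "ipa"))
    expect_identical(rep$scenarios[[m]][1], unname(ref[[m]]))
})

test_that("systematic-only heterogeneity leaves discrimination unchanged but moves calibration directionally", {
  s <- make_qpea_setup()
  grid <- as_scenario_grid(data.frame(psi = c(-0.3, 0, 0.3, 0, 0),
                                      theta = c(1, 1, 1, 0.5, 2),
                                      sigma_eps = 0))
  cfg <- qpea_config("x", grid, horizon = 6.5, n_bootstrap = 0, seed = 3)
  rep <- run_scenarios(s$cohort, s$model, cfg)
  sc <- rep$scenarios

  # additive and multiplicative shifts are monotone marker transforms:
  # the cumulative-dynamic AUC is identical across them
  expect_equal(diff(range(sc$auc)), 0, tolerance = 1e-12)

  # a higher measured value at implementation overstates risk: O/E < 1
  expect_lt(sc$oe_ratio[sc$psi == 0.3 & sc$theta == 1], 1)
  expect_gt(sc$oe_ratio[sc$psi == -0.3 & sc$theta == 1], 1)
  expect_lt(sc$oe_ratio[sc$theta == 2], 1)

  # accuracy degrades as theta departs from 1 in either direction
  ipa_home <- sc$ipa[sc$psi == 0 & sc$theta == 1]
  expect_gt(ipa_home, sc$ipa[sc$theta == 0.5])
  expect_gt(ipa_home, sc$ipa[sc$theta == 2])
})

test_that("random heterogeneity degrades discrimination monotonically", {
  s <- make_qpea_setup()
  grid <- as_scenario_grid(data.frame(psi = 0, theta = 1,
                                      sigma_eps = c(0, sqrt(2) / 2, sqrt(2))))
  cfg <- qpea_config("x", grid, horizon = 6.5, n_bootstrap = 0, seed = 4)
  rep <- run_scenarios(s$cohort, s$model, cfg)
  expect_true(all(diff(rep$scenarios$auc) < 0))
  expect_true(all(diff(rep$scenarios$ipa) < 0))
})

test_that("marginal bands are min/max envelopes with inner contained in outer", {
  s <- make_qpea_setup(n = 1500)
  grid <- scenario_grid(c(-1, 0), c(0.9, 1), c(0, 1.5), levels = 2)
  grid <- as_scenario_grid(rbind(as.data.frame(grid)[, -1],
                                 data.frame(psi = -0.5, theta = 0.95,
                                            sigma_eps = 0.75)))
  cfg <- qpea_config("x", grid, horizon = 6.5, n_bootstrap = 40, seed = 5)
  rep <- run_scenarios(s$cohort, s$model, cfg)
  bands <- rep$bands
  expect_true(all(bands$inner_min <= bands$inner_max))
  expect_true(all(bands$outer_min <= bands$inner_min))
  expect_true(all(bands$inner_max <= bands$outer_max))
  expect_setequal(unique(bands$sigma_eps), c(0, 0.75, 1.5))

  # independent re-aggregation from the per-scenario table
  sc <- rep$scenarios
  for (sg in unique(bands$sigma_eps)) {
    sub <- sc[sc$sigma_eps == sg, ]
    b <- bands[bands$sigma_eps == sg & bands$metric == "auc", ]
    expect_identical(b$inner_min, min(sub$auc))
    expect_identical(b$inner_max, max(sub$auc))
    expect_identical(b$outer_min, min(sub$auc_lower, sub$auc))
    expect_identical(b$outer_max, max(sub$auc_upper, sub$auc))
  }

  # a single-scenario report collapses to zero-width inner bands
  one <- run_scenarios(s$cohort, s$model,
                       qpea_config("x", as_scenario_grid(
                         data.frame(psi = 0, theta = 1, sigma_eps = 0)),
                         horizon = 6.5, n_bootstrap = 0, seed = 6))
  expect_true(all(one$bands$inner_min == one$bands$inner_max))
})

test_that("scenario runs are reproducible and robust to undefined scenarios", {
  s <- make_qpea_setup(n = 1200)
  grid <- as_scenario_grid(data.frame(psi = c(0, 0), theta = c(1, 1.5),
                                      sigma_eps = c(0.5, 1)))
  cfg <- qpea_config("x", grid, horizon = 6.5, n_bootstrap = 25, seed = 7)
  r1 <- run_scenarios(s$cohort, s$model, cfg)
  r2 <- run_scenarios(s$cohort, s$model, cfg)
  expect_identical(r1$scenarios, r2$scenarios)

  # a scenario whose predictions all collapse to survival 1 has an undefined
  # O/E ratio: recorded missing with a warning, the run continues
  gridbad <- as_scenario_grid(data.frame(psi = c(-1e6, 0), theta = 1,
                                         sigma_eps = 0))
  cfg2 <- qpea_config("x", gridbad, horizon = 6.5, n_bootstrap = 0, seed = 8)
  expect_warning(repbad <- run_scenarios(s$cohort, s$model, cfg2),
                 "recorded as missing")
  expect_true(is.na(repbad$scenarios$oe_ratio[1]))
  expect_false(is.na(repbad$scenarios$oe_ratio[2]))

  expect_error(run_scenarios(s$cohort, s$model,
                             qpea_config("nope", grid, 6.5, n_bootstrap = 0)),
               class = "hetsurv_schema_error")
})

test_that("rendered reports are complete and byte-deterministic", {
  s <- make_qpea_setup(n = 1000)
  grid <- scenario_grid(c(-0.3, 0), c(1, 1.2), c(0, 1), levels = 2)
  cfg <- qpea_config("x", grid, horizon = 6.5, n_bootstrap = 20, seed = 9,
                     prediction_target_text = "Risk of the event by t = 6.5.")
  rep <- run_scenarios(s$cohort, s$model, cfg)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  render_report(rep, d1)
  render_report(rep, d2)
  expect_true(all(c("scenario_metrics.csv", "bands.csv", "report.txt",
                    "fig_auc.png", "fig_oe_ratio.png") %in% list.files(d1)))
  for (f in c("scenario_metrics.csv", "bands.csv", "report.txt"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  txt <- readLines(file.path(d1, "report.txt"))
  expect_true(any(grepl("Risk of the event by t = 6.5.", txt, fixed = TRUE)))
  # empty free-text fields render as placeholders
  expect_true(any(grepl("[to be completed by the analyst]", txt, fixed = TRUE)))
  expect_true(any(grepl("^7\\. ", txt)))
})
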