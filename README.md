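# hetsurv

Quantify how **predictor measurement heterogeneity** — a predictor being
measured differently in the clinic where a model is deployed than in the
study where it was validated — degrades the out-of-sample performance of
time-to-event prediction models.

The package is for biostatisticians and epidemiologists running external
validation studies of prognostic models. A model validated with
scale-measured BMI may be implemented with self-reported BMI; the model
itself does not change, but its calibration, discrimination and accuracy
at implementation do. `hetsurv` lets you anticipate that change before
implementation by simulation over plausible measurement scenarios.

## The model at the core

Validation-setting measurements $X$ and implementation-setting
measurements $W$ of the same predictor are linked by a linear measurement
model

$$W = \psi + \theta X + \epsilon, \qquad \epsilon \sim N(0, \sigma_\epsilon^2),$$

with an additive systematic shift $\psi$, a multiplicative systematic
association $\theta$, and extra random measurement variation
$\sigma_\epsilon$; $(0, 1, 0)$ is measurement homogeneity. A
proportional-hazards prediction model $S(t \mid x) = S_0(t)^{\exp(\beta'
x)}$ is evaluated **as-is** on cohorts whose flagged predictor has been
pushed through this model, over a factorial grid of
$(\psi, \theta, \sigma_\epsilon)$ scenarios. Performance at a fixed
horizon $t$ is summarized by:

* **O/E ratio** — observed (Kaplan-Meier) over mean predicted event
  probability at $t$; 1 = mean calibration, < 1 = risks overestimated;
* **AUC(t)** — cumulative-dynamic time-dependent AUC with inverse
  probability of censoring weights (reverse Kaplan-Meier);
* **Brier(t)** and **IPA(t)** — IPCW Brier score and the index of
  prediction accuracy $1 - \text{Brier}_{model}/\text{Brier}_{null}$
  against the null model predicting the marginal Kaplan-Meier risk;

each with percentile bootstrap confidence intervals. A cohort simulator
(standard-normal predictor, exponential event times via cumulative-hazard
inversion, administrative and/or random censoring), exponential and Cox
fitting, baseline recalibration by linear-predictor offset, and a
seven-step "quantitative prediction error analysis" reporting workflow are
included. See the vignette in `vignettes/measurement-heterogeneity.Rmd`
for the full methodology.

## Worked example

Derive a Cox model on one simulated cohort, validate it on another, then
ask what happens if the predictor is measured differently at
implementation:

```r
library(hetsurv)

derivation <- generate_cohort(dgm_config(n = 1e5, censoring = "administrative", seed = 2024))
validation <- generate_cohort(dgm_config(n = 1e5, censoring = "administrative", seed = 2025))

model <- fit_cox(derivation, "x")
validate_model(model, validation, horizon = 6.5, n_bootstrap = 200, seed = 1)
#> Performance at t = 6.5 (n = 100000)
#>   oe_ratio       0.9986  [0.9930, 1.0045]
#>   auc            0.7382  [0.7355, 0.7413]
#>   brier_model    0.2066  [0.2056, 0.2076]
#>   brier_null     0.2500  [0.2499, 0.2500]
#>   ipa            0.1735  [0.1696, 0.1775]
```

Under measurement homogeneity the model is well calibrated on average
(O/E ≈ 1), discriminates with AUC(6.5) ≈ 0.74 and improves on the null
model by IPA ≈ 0.17. Now sweep a 27-scenario grid of anticipated
heterogeneity in the predictor and marginalize into bands:

```r
grid <- scenario_grid(psi_range = c(-0.3, 0.3), theta_range = c(0.5, 2),
                      sigma_range = c(0, sqrt(2)), levels = 3)
cfg <- qpea_config("x", grid, horizon = 6.5, n_bootstrap = 100, seed = 7)
report <- run_scenarios(validation[1:20000, ], model, cfg)
subset(report$bands, metric %in% c("oe_ratio", "auc", "ipa"))
#>    sigma_eps   metric inner_min inner_max outer_min outer_max
#> 1      0.000 oe_ratio    0.8806    1.1812   0.86595   1.19902
#> 2      0.000      auc    0.7362    0.7362   0.72937   0.74373
#> 5      0.000      ipa    0.0931    0.1646   0.07790   0.17672
#> 6      0.707 oe_ratio    0.8782    1.1454   0.86916   1.15853
#> 7      0.707      auc    0.6311    0.7237   0.62639   0.72972
#> 10     0.707      ipa    0.0132    0.0998   0.00661   0.10505
#> 11     1.414 oe_ratio    0.8788    1.0841   0.86940   1.10429
#> 12     1.414      auc    0.5760    0.6899   0.56821   0.69967
#> 15     1.414      ipa   -0.1740   -0.0266  -0.18822  -0.00677
```

Reading the bands: systematic shifts alone (`sigma_eps = 0` row) move
calibration-in-the-large across roughly 0.88–1.18 while leaving the AUC
untouched (it depends on the marker only through ranks); random
heterogeneity (`sigma_eps > 0`) is what erodes discrimination (AUC
sliding from 0.74 toward 0.58) and can push the IPA negative — a model
worse than using no patient information. `render_report(report, "out/")`
writes the per-scenario table, band table, banded figures and a
seven-step report skeleton.

A command-line interface covering the same pipeline
(`simulate`, `fit`, `validate`, `qpea`, `fixture`) is installed at
`inst/cli/hetsurv`.

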