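# biogasdlm

Self-learning, data-driven simulation of biogas production in full-scale
anaerobic digesters.

## The problem

Biogas plants that are paid to produce power on demand must plan their
feeding so that gas arrives when it is needed. Mechanistic digestion models
(ADM1-family) can simulate this but require dozens of biochemical
parameters that are practically never available for a full-scale plant.
`biogasdlm` instead uses only what every plant already logs hourly: the
mass of solid substrate fed (kg h⁻¹) and the biogas produced at standard
conditions (m³ h⁻¹) — no differentiation of individual substrates, no
process measurements.

## The model

Production is a finite distributed-lag regression on current and past
feeding, fitted by ordinary least squares:

$$Y_t = \alpha + \beta_0 X_t + \beta_1 X_{t-1} + \dots + \beta_k X_{t-k} + \varepsilon_t$$

* **Self-learning:** before every simulation the model is refit on the
  `train_length` most recent hours (default T = 500), so it tracks the
  digester's drifting state without manual recalibration.
* **Forecasting:** an `horizon`-hour simulation (default H = 48) is a
  single linear pass over the planned feeding schedule — there are no
  autoregressive terms, hence no error recursion.
* **Evaluation:** rolling-origin replay over a year with daily refits,
  scored by MAPE, MAE and RMSE per run and averaged per settings cell
  (T × k × H grid).
* **Kinetics:** across a few hundred rolling fits, the per-lag median of
  the β coefficients traces the substrate's gas-formation curve
  (m³ kg⁻¹ per hour after feeding); its cumulative sum is the specific
  biogas yield within the lag window.

Because real plant records of this kind are operator data and not public,
the package includes a calibrated synthetic plant generator
(`plant_scenario()` / `generate_plant()`) with exactly known ground truth —
the validation backbone of the test suite, and a realistic sandbox for
method exploration.

## Worked example

```r
library(biogasdlm)

# one synthetic operating year: ~6,000 kg/d solid feed in discrete events,
# gas response with 62% released within 12 h, baseline, noise, downtime
sim <- generate_plant(plant_scenario(duration = 8760, seed = 1))

# 1. screening: does lagged feeding predict production?
significant_lags(cross_correlate(sim$series, max_lag = 48))
#> # A tibble: 74 × 3
#>     lag correlation sign
#>   <int>       <dbl> <chr>
#> 1     3       0.282 positive
#> 2     4       0.278 positive
#> 3     5       0.271 positive

# 2. one self-learning fit
fit <- fit_dlm(sim$series, dlm_config(train_length = 500, lag_order = 48),
               train_end = 4000)
fit
#> <biogas_dlm> k = 48, T = 500, regressors: solid_feed
#>   alpha = 43.696 m3/h, sigma = 4.878, R^2 = 0.8600, trained to 2018-06-16T15:00:00

# 3. a year of rolling 48-h simulations, refit every 24 h
runs <- rolling_evaluate(sim$series,
                         dlm_config(train_length = 500, lag_order = 48,
                                    horizon = 48))
summarise_runs(runs)
#> # A tibble: 1 × 7
#>   n_runs n_failed success_fraction  mape  rmse   mae excluded_zero_hours
#> 1    341        0                1  6.52  6.01  4.89                  90

# 4. gas-formation kinetics from the fitted coefficients
auc_yield(median_curve(collect_coefficients(runs)), window = 49)
#> <auc_yield> 0.1000 m3 biogas per kg substrate within 49 h
#>   fraction released by hour 12: 62.6%
```

Reading the numbers: a mean absolute percentage error of **6.5%** over 341
independent 48-h hindcasts (90 plant-downtime hours excluded from the
percentage metric, none from MAE/RMSE); the recovered specific yield of
**0.100 m³ kg⁻¹** and 12-h release fraction of **62.6%** reproduce the
generator's ground-truth kernel (0.101 m³ kg⁻¹, 62%) — on real digesters
the same analysis reads the substrate's gas-formation kinetics out of
routine operating data. `autoplot()` methods exist for series, fits,
cross-correlations, coefficient ensembles and grid reports;
`grid_report()` compares all 27 combinations of T ∈ {200, 500, 800},
k ∈ {48, 72, 96}, H ∈ {48, 96, 144}.

A thin command-line front end over the same functions lives at
`inst/cli/biogasdlm.R` (subcommands `synth`, `ccf`, `fit`, `simulate`,
`evaluate`, `kinetics`).

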