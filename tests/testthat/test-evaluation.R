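test_that("metrics reproduce hand-computed values", {
  expect_equal(as.numeric(mape(c(10, 20), c(11, 18))), 10)
  expect_equal(mae(c(10, 20), c(11, 18)), 1.5)
  expect_equal(rmse(c(10, 20), c(11, 18)), sqrt(2.5))
  # perfect simulation
  z <- c(55.2, 70.1, 64.4)
  expect_equal(as.numeric(mape(z, z)), 0)
  expect_equal(mae(z, z), 0)
  expect_equal(rmse(z, z), 0)
  # constant offset passes straight through the MAE
  expect_equal(mae(z, z + 3.25), 3.25)
})

test_that("observed zeros are excluded from MAPE but kept in MAE/RMSE", {
  m <- mape(c(0, 10), c(0, 11))
  expect_equal(as.numeric(m), 10)
  expect_equal(attr(m, "excluded_zero_hours"), 1)
  expect_equal(attr(m, "n_used"), 1)
  # MAE/RMSE keep the zero hour
  expect_equal(mae(c(0, 10), c(4, 11)), 2.5)
  expect_error(mape(c(0, 0), c(1, 2)), class = "biogasdlm_error_metric")
  row <- accuracy_metrics(c(0, 10), c(0, 11))
  expect_equal(row$excluded_zero_hours, 1)
  expect_equal(row$n, 2)
})

test_that("rmse >= mae on arbitrary inputs and lengths must agree", {
  set.seed(20)
  for (i in 1:200) {
    E <- sample(1:60, 1)
    z <- abs(rnorm(E, 60, 25))
    zs <- z + rnorm(E, 0, 10)
    expect_gte(rmse(z, zs), mae(z, zs))
  }
  expect_error(mae(1:3, 1:4), class = "biogasdlm_error_schema")
  expect_error(rmse(numeric(0), numeric(0)), class = "biogasdlm_error_bounds")
})

test_that("run counts match the closed-form counting oracle exactly", {
  # brute-force enumeration oracle
  enumerate <- function(n, T_len, k, H, step) {
    if (T_len + k > n) return(0L)
    origins <- seq.int(T_len + k, n, by = step)
    sum(origins + H <= n)
  }
  set.seed(30)
  for (i in 1:200) {
    n <- sample(100:9000, 1)
    T_len <- sample(c(200, 500, 800), 1)
    k <- sample(c(48, 72, 96), 1)
    H <- sample(c(48, 96, 144), 1)
    step <- sample(c(1, 6, 24), 1)
    expect_equal(count_origins(n, T_len, k, H, step),
                 enumerate(n, T_len, k, H, step))
  }
  # worked case: a full year at the usual settings
  expect_equal(count_origins(8760, 500, 48, 48, 24), 341L)
})

test_that("rolling evaluation visits exactly the predicted origins", {
  sim <- generate_plant(noiseless_scenario(1000, seed = 12))
  cfg <- dlm_config(train_length = 500, lag_order = 48, horizon = 48)
  runs <- rolling_evaluate(sim$series, cfg, keep_models = FALSE)
  expect_equal(nrow(runs), count_origins(1000, 500, 48, 48, 24))
  expect_equal(runs$origin_index[1], 548)
  expect_true(all(diff(runs$origin_index) == 24))

  # a series exactly T + k + H long admits exactly one run
  sim1 <- generate_plant(noiseless_scenario(596, seed = 13))
  runs1 <- rolling_evaluate(sim1$series,
                            dlm_config(train_length = 500, lag_order = 48,
                                       horizon = 48))
  expect_equal(nrow(runs1), 1)

  # and one hour less admits none
  short <- slice_window(sim1$series, end = 595, length = 595)
  expect_error(rolling_evaluate(short, cfg),
               class = "biogasdlm_error_evaluation")
})

test_that("noiseless synthetic data yield near-zero error in every run", {
  sim <- generate_plant(noiseless_scenario(900, seed = 14))
  runs <- rolling_evaluate(sim$series,
                           dlm_config(train_length = 500, lag_order = 48,
                                      horizon = 48))
  expect_true(all(runs$status == "ok"))
  expect_true(all(runs$mape < 1e-6))
})

test_that("singular training windows are recorded as failed runs, not dropped", {
  n <- 596
  ps <- make_series(n, solid = rep(0, n),
                    biogas = abs(rnorm(n, 65, 5)))
  runs <- rolling_evaluate(ps, dlm_config(train_length = 500, lag_order = 48,
                                          horizon = 48))
  expect_equal(nrow(runs), 1)
  expect_equal(runs$status, "singular")
  expect_match(runs$failure, "solid_feed_lag")
  s <- summarise_runs(runs)
  expect_equal(s$n_failed, 1)
  expect_equal(s$success_fraction, 0)
})

test_that("per-cell grid means equal independently recomputed run means", {
  sim <- generate_plant(plant_scenario(duration = 900, seed = 15))
  cfg <- dlm_config(train_length = 200, lag_order = 48, horizon = 48)
  runs <- rolling_evaluate(sim$series, cfg, keep_models = FALSE)
  cell <- grid_report(sim$series, train_lengths = 200, lag_orders = 48,
                      horizons = 48)
  expect_equal(cell$mape, mean(runs$mape))
  expect_equal(cell$rmse, mean(runs$rmse))
  expect_equal(cell$mae, mean(runs$mae))
  expect_equal(cell$n_runs, nrow(runs))
})

test_that("shared-fit horizon columns equal truncated rescoring of the long runs", {
  sim <- generate_plant(plant_scenario(duration = 1100, seed = 16))
  rep_shared <- grid_report(sim$series, train_lengths = 200, lag_orders = 48,
                            horizons = c(24, 48))
  runs48 <- rolling_evaluate(sim$series,
                             dlm_config(train_length = 200, lag_order = 48,
                                        horizon = 48), keep_models = FALSE)
  manual24 <- vapply(seq_len(nrow(runs48)), function(i) {
    rmse(runs48$observed[[i]][1:24], runs48$simulated[[i]][1:24])
  }, numeric(1))
  expect_equal(rep_shared$rmse[rep_shared$horizon == 24], mean(manual24))
  # both horizons share the same origin count
  expect_equal(unique(rep_shared$n_runs), nrow(runs48))
})

test_that("independent-fit mode admits more origins for shorter horizons", {
  sim <- generate_plant(plant_scenario(duration = 900, seed = 18))
  rep_ind <- grid_report(sim$series, train_lengths = 200, lag_orders = 48,
                         horizons = c(24, 96), share_fits = FALSE)
  n24 <- rep_ind$n_runs[rep_ind$horizon == 24]
  n96 <- rep_ind$n_runs[rep_ind$horizon == 96]
  expect_equal(n24, count_origins(900, 200, 48, 24, 24))
  expect_equal(n96, count_origins(900, 200, 48, 96, 24))
  expect_gt(n24, n96)
})

test_that("mean RMSE is non-decreasing in the horizon on noisy data", {
  # prefix truncation: fewer hours bias the root downward (concavity), so
  # the cell mean grows weakly with H; checked on the mean across seeds
  deltas <- vapply(1:12, function(s) {
    sim <- generate_plant(plant_scenario(duration = 800, seed = 100 + s))
    rep <- grid_report(sim$series, train_lengths = 200, lag_orders = 48,
                       horizons = c(24, 48, 96))
    diff(rep$rmse[order(rep$horizon)])
  }, numeric(2))
  expect_true(all(rowMeans(deltas) > -1e-8))
})

test_that("grid_wide pivots to the report layout", {
  sim <- generate_plant(plant_scenario(duration = 900, seed = 19))
  rep <- grid_report(sim$series, train_lengths = c(200, 300),
                     lag_orders = 48, horizons = c(24, 48))
  w <- grid_wide(rep, "mape")
  expect_identical(names(w), c("train_length", "lag_order", "H24", "H48"))
  expect_equal(nrow(w), 2)
})
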