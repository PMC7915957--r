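test_that("config guards its invariants", {
  expect_s3_class(dlm_config(), "dlm_config")
  expect_error(dlm_config(lag_order = -1), class = "biogasdlm_error_config")
  expect_error(dlm_config(horizon = 0), class = "biogasdlm_error_config")
  # T must exceed the parameter count 1 + (k+1) * n_regressors
  expect_error(dlm_config(lag_order = 48, train_length = 50),
               class = "biogasdlm_error_config")
  expect_error(dlm_config(regressors = c("solid_feed", "solid_feed")),
               class = "biogasdlm_error_config")
})

test_that("design matrix has the specified shape and column order", {
  sim <- generate_plant(noiseless_scenario(700, seed = 1))
  d <- build_design(sim$series, dlm_config(train_length = 500, lag_order = 48),
                    train_end = 600)
  expect_equal(dim(d$matrix), c(500, 50))
  expect_identical(colnames(d$matrix)[1:3],
                   c("(Intercept)", "solid_feed_lag0", "solid_feed_lag1"))
  expect_true(all(d$matrix[, 1] == 1))

  # degenerate lag order 0: just intercept and same-hour feeding
  ps <- make_series(6, solid = c(1, 2, 3, 4, 5, 6), biogas = 1:6)
  d0 <- build_design(ps, dlm_config(lag_order = 0, train_length = 3),
                     train_end = 6)
  expect_identical(colnames(d0$matrix), c("(Intercept)", "solid_feed_lag0"))
  expect_equal(d0$matrix[, "solid_feed_lag0"], c(4, 5, 6))
  expect_equal(d0$response, c(4, 5, 6))

  # two regressors: 1 + 2 * 49 columns
  sim2 <- generate_plant(plant_scenario(duration = 400, seed = 2,
                                        liquid = liquid_spec()))
  d2 <- build_design(sim2$series,
                     dlm_config(train_length = 200, lag_order = 48,
                                regressors = c("solid_feed", "liquid_feed")),
                     train_end = 300)
  expect_equal(ncol(d2$matrix), 99)
})

test_that("lagged values are the actually observed history, never zero-padding", {
  n <- 30
  solid <- seq(100, by = 10, length.out = n)
  ps <- make_series(n, solid = solid, biogas = rep(60, n))
  d <- build_design(ps, dlm_config(lag_order = 5, train_length = 10),
                    train_end = 25)
  rows <- 16:25
  for (j in 0:5) {
    expect_equal(unname(d$matrix[, paste0("solid_feed_lag", j)]),
                 solid[rows - j])
  }
  expect_error(build_design(ps, dlm_config(lag_order = 5, train_length = 10),
                            train_end = 14),
               class = "biogasdlm_error_bounds")
  expect_error(build_design(ps, dlm_config(lag_order = 5, train_length = 10,
                                           regressors = "liquid_feed"),
                            train_end = 25),
               class = "biogasdlm_error_schema")
})

test_that("a noiseless linear law is recovered exactly at lag order 0", {
  x <- c(3, 7, 1, 9, 4, 6, 2, 8)
  ps <- make_series(8, solid = x, biogas = 2 + 0.5 * x)
  fit <- fit_dlm(ps, dlm_config(lag_order = 0, train_length = 8))
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
  expect_equal(unname(fit$betas$solid_feed), 0.5, tolerance = 1e-10)
  expect_equal(mean(fit$residuals), 0, tolerance = 1e-12)
})

test_that("QR solution equals the explicit normal-equations solution", {
  set.seed(42)
  for (i in 1:10) {
    n <- 200
    k <- 8
    solid <- abs(rnorm(n + k, 500, 300))
    beta <- runif(k + 1, 0, 0.01)
    full <- c(rep(0, k), solid)
    y <- 30 + as.numeric(stats::filter(full, beta, method = "convolution",
                                       sides = 1))[(k + 1):(k + n + k)] +
      rnorm(n + k, sd = 2)
    ps <- make_series(n + k, solid = solid, biogas = pmax(y, 0))
    d <- build_design(ps, dlm_config(lag_order = k, train_length = n),
                      train_end = n + k)
    fit <- fit_dlm(d)
    oracle <- solve(crossprod(d$matrix), crossprod(d$matrix, d$response))
    expect_equal(unname(fit$coefficients), unname(drop(oracle)), tolerance = 1e-8)
  }
})

test_that("noiseless synthetic data return the generating kernel and baseline", {
  sim <- generate_plant(noiseless_scenario(700, seed = 9))
  fit <- fit_dlm(sim$series, dlm_config(train_length = 500, lag_order = 48))
  expect_equal(fit$alpha, sim$truth$alpha_true, tolerance = 1e-6)
  expect_equal(unname(fit$betas$solid_feed), sim$truth$kernel,
               tolerance = 1e-6)
})

test_that("rank deficiency is a loud error naming the offending columns", {
  # zero feeding throughout the training window
  ps <- make_series(60, solid = rep(0, 60), biogas = rep(65, 60))
  err <- expect_error(
    fit_dlm(ps, dlm_config(lag_order = 2, train_length = 50)),
    class = "biogasdlm_error_singular"
  )
  expect_match(conditionMessage(err), "solid_feed_lag")
})

test_that("simulation evaluates the distributed-lag sum over planned and historical feeding", {
  sim <- generate_plant(noiseless_scenario(700, seed = 4))
  cfg <- dlm_config(train_length = 500, lag_order = 48, horizon = 48)
  fit <- fit_dlm(sim$series, cfg)

  # all-zero future and history: constant alpha
  out <- simulate_biogas(fit, rep(0, 48), rep(0, 48))
  expect_equal(out$simulated, rep(fit$alpha, 48), tolerance = 1e-9)

  # impulse response: 1 kg at future hour 0 with alpha forced to 0
  fit0 <- fit
  fit0$alpha <- 0
  imp <- simulate_biogas(fit0, c(1, rep(0, 48)), rep(0, 48), clamp = FALSE)
  expect_equal(imp$simulated[1:49], unname(fit$betas$solid_feed),
               tolerance = 1e-9)

  # hindcast on the recorded feeding reproduces noiseless production
  i <- 600
  planned <- sim$series[(i + 1):(i + 48), "solid_feed"]
  history <- sim$series[(i - 47):i, "solid_feed"]
  yhat <- simulate_biogas(fit, planned, history)$simulated
  expect_equal(yhat, sim$series$biogas[(i + 1):(i + 48)], tolerance = 1e-6)
})

test_that("simulation is linear in the planned feeding when alpha = 0 and clamp off", {
  sim <- generate_plant(noiseless_scenario(700, seed = 6))
  fit <- fit_dlm(sim$series, dlm_config(train_length = 500, lag_order = 48))
  fit$alpha <- 0
  set.seed(10)
  f1 <- abs(rnorm(48, 300, 200))
  f2 <- abs(rnorm(48, 300, 200))
  hist0 <- rep(0, 48)
  s <- function(f) simulate_biogas(fit, f, hist0, clamp = FALSE)$simulated
  expect_equal(s(2 * f1 + 3 * f2), 2 * s(f1) + 3 * s(f2), tolerance = 1e-9)
})

test_that("clamping truncates negative predictions at zero", {
  cfg <- dlm_config(lag_order = 0, train_length = 10, horizon = 4)
  design <- structure(
    list(response = c(-1, -2.2, -3, -4.1, -5, -6, -7.3, -8, -9, -10.2),
         matrix = cbind(`(Intercept)` = rep(1, 10),
                        solid_feed_lag0 = 1:10),
         config = cfg,
         train_end = as.POSIXct("2018-01-01", tz = "UTC")),
    class = "dlm_design"
  )
  fit <- fit_dlm(design)  # alpha near 0, beta near -1
  expect_lt(fit$alpha, 1)
  clamped <- simulate_biogas(fit, rep(5, 4))
  expect_true(all(clamped$simulated == 0))
  free <- simulate_biogas(fit, rep(5, 4), clamp = FALSE)
  expect_true(all(free$simulated < 0))
})

test_that("simulation input contracts are enforced", {
  sim <- generate_plant(noiseless_scenario(700, seed = 8))
  fit <- fit_dlm(sim$series, dlm_config(train_length = 500, lag_order = 48))
  expect_error(simulate_biogas(fit, rep(0, 48), rep(0, 10)),
               class = "biogasdlm_error_bounds")
  expect_error(simulate_biogas(fit, tibble::tibble(wrong = rep(0, 48)),
                               rep(0, 48)),
               class = "biogasdlm_error_schema")
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- generate_plant(noiseless_scenario(700, seed = 3))
  fit <- fit_dlm(sim$series, dlm_config(train_length = 500, lag_order = 48))
  td <- tidy(fit)
  expect_equal(nrow(td), 50)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(td$lag[-1], 0:48)
  gl <- glance(fit)
  expect_equal(gl$nobs, 500)
  expect_equal(gl$df.residual, 450)
  expect_gt(gl$r.squared, 0.99)
})
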