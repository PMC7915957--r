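#' Simulation accuracy metrics
#'
#' Mean absolute percentage error, mean absolute error, and root mean squared
#' error between observed and simulated biogas production:
#' \deqn{MAPE = \frac{1}{E}\sum_t \left|\frac{z_t - z^s_t}{z_t}\right| \times 100\%}
#' \deqn{MAE = \frac{1}{E}\sum_t |z_t - z^s_t|, \qquad
#'       RMSE = \sqrt{\frac{1}{E}\sum_t (z_t - z^s_t)^2}}
#'
#' Hours with observed production exactly zero (genuine plant downtime) are
#' excluded from the MAPE sum — the percentage error is undefined there —
#' and `E` is reduced accordingly; MAE and RMSE retain all hours. The number
#' of excluded hours is reported as attribute `excluded_zero_hours` on the
#' MAPE value and as a column of [accuracy_metrics()].
#'
#' @param observed Vector of observed values `z` (m^3 h^-1).
#' @param simulated Vector of simulated values `z^s`, same length.
#' @return `mape()`: percentage (with attributes `excluded_zero_hours`,
#'   `n_used`); `mae()`, `rmse()`: m^3 h^-1. `accuracy_metrics()`: a one-row
#'   tibble with all three plus `n` and `excluded_zero_hours`.
#' @examples
#' mape(c(10, 20), c(11, 18))  # 10%
#' mae(c(10, 20), c(11, 18))   # 1.5
#' rmse(c(10, 20), c(11, 18))  # sqrt(2.5)
#' @export
mape <- function(observed, simulated) {
  check_metric_inputs(observed, simulated)
  nonzero <- observed != 0
  excluded <- sum(!nonzero)
  if (!any(nonzero)) {
    rlang::abort("MAPE undefined: all observed values are zero.",
                 class = "biogasdlm_error_metric")
  }
  z <- observed[nonzero]
  zs <- simulated[nonzero]
  out <- mean(abs((z - zs) / z)) * 100
  structure(out, excluded_zero_hours = excluded, n_used = length(z))
}

#' @rdname mape
#' @export
mae <- function(observed, simulated) {
  check_metric_inputs(observed, simulated)
  mean(abs(observed - simulated))
}

#' @rdname mape
#' @export
rmse <- function(observed, simulated) {
  check_metric_inputs(observed, simulated)
  sqrt(mean((observed - simulated)^2))
}

#' @rdname mape
#' @export
accuracy_metrics <- function(observed, simulated) {
  check_metric_inputs(observed, simulated)
  nonzero <- observed != 0
  mape_val <- if (any(nonzero)) {
    as.numeric(mape(observed, simulated))
  } else {
    NA_real_
  }
  tibble::tibble(
    mape = mape_val,
    mae = mae(observed, simulated),
    rmse = rmse(observed, simulated),
    n = length(observed),
    excluded_zero_hours = sum(!nonzero)
  )
}

check_metric_inputs <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    abort_schema(sprintf("Length mismatch: %d observed vs %d simulated.",
                         length(observed), length(simulated)))
  }
  if (length(observed) < 1) {
    abort_bounds("Metrics need at least one observation.")
  }
  invisible(TRUE)
}

#' Number of rolling-origin runs a series supports
#'
#' Closed form for the number of valid forecast origins on a fixed-step grid:
#' the first origin needs `train_length + lag_order` hours of history, each
#' origin needs `horizon` hours of future data, and consecutive origins are
#' `step` hours apart, giving
#' `floor((n - (T + k) - H) / step) + 1` runs (0 when negative).
#'
#' @param n Series length in hours.
#' @param train_length,lag_order,horizon Model settings T, k, H.
#' @param step Hours between forecast origins (24 = daily refit).
#' @return Integer run count.
#' @export
count_origins <- function(n, train_length, lag_order, horizon, step = 24) {
  slack <- n - (train_length + lag_order) - horizon
  if (slack < 0) return(0L)
  as.integer(slack %/% step + 1L)
}

#' Rolling-origin evaluation of the self-learning model
#'
#' Replays a year (or any span) of plant operation: at every forecast origin
#' on a `step`-hour grid the model is refit on the `train_length` most recent
#' observations (with `lag_order` warm-up rows before them), production over
#' the next `horizon` hours is simulated using the *recorded* feeding as the
#' planned schedule (a hindcast), and the simulation is scored against the
#' recorded production. Origins whose training window yields a singular
#' design (e.g. no feeding variation) are recorded as failed runs, never
#' silently dropped.
#'
#' @param series A [plant_series].
#' @param config A [dlm_config].
#' @param step Hours between forecast origins; 24 refits once per day.
#' @param keep_models Keep each run's fitted model in a list column (needed
#'   for [collect_coefficients()]); switch off to save memory.
#' @return A tibble of class `dlm_runs`, one row per origin: `origin`
#'   (timestamp of the last training observation), `origin_index`, `status`
#'   (`"ok"`/`"singular"`), `mape`, `mae`, `rmse`, `excluded_zero_hours`,
#'   plus list columns `observed`, `simulated` and (optionally) `model`.
#'   Attributes: `config`, `step`.
#' @examples
#' sim <- generate_plant(plant_scenario(duration = 2000, seed = 3))
#' runs <- rolling_evaluate(sim$series,
#'                          dlm_config(train_length = 500, lag_order = 48,
#'                                     horizon = 48))
#' summarise_runs(runs)
#' @export
rolling_evaluate <- function(series, config, step = 24, keep_models = TRUE) {
  stopifnot(is_plant_series(series), inherits(config, "dlm_config"))
  n <- nrow(series)
  T_len <- config$train_length
  k <- config$lag_order
  H <- config$horizon
  first_origin <- T_len + k
  last_origin <- n - H
  if (first_origin > last_origin) {
    rlang::abort(sprintf(
      "No valid forecast origin: series of %d h cannot host T + k = %d history plus H = %d future hours.",
      n, T_len + k, H
    ), class = "biogasdlm_error_evaluation")
  }
  origins <- seq.int(first_origin, last_origin, by = step)
  runs <- purrr::map(origins, function(i) {
    fit <- tryCatch(
      fit_dlm(build_design(series, config, train_end = i)),
      biogasdlm_error_singular = function(e) e
    )
    obs <- series$biogas[(i + 1):(i + H)]
    if (inherits(fit, "error")) {
      return(tibble::tibble(
        origin = series$timestamp[i], origin_index = i, status = "singular",
        mape = NA_real_, mae = NA_real_, rmse = NA_real_,
        excluded_zero_hours = NA_integer_,
        observed = list(obs), simulated = list(NULL),
        model = list(NULL), failure = conditionMessage(fit)
      ))
    }
    planned <- series[(i + 1):(i + H), config$regressors, drop = FALSE]
    history <- series[(i - k + 1):i, config$regressors, drop = FALSE]
    sim <- simulate_biogas(fit, planned, history)$simulated
    m <- accuracy_metrics(obs, sim)
    tibble::tibble(
      origin = series$timestamp[i], origin_index = i, status = "ok",
      mape = m$mape, mae = m$mae, rmse = m$rmse,
      excluded_zero_hours = m$excluded_zero_hours,
      observed = list(obs), simulated = list(sim),
      model = list(if (keep_models) fit else NULL), failure = NA_character_
    )
  })
  out <- dplyr::bind_rows(runs)
  if (!keep_models) out$model <- NULL
  tibble::new_tibble(out, config = config, step = step,
                     digester_id = attr(series, "digester_id"),
                     class = "dlm_runs")
}

#' @describeIn rolling_evaluate Mean per-run accuracy across successful runs,
#'   with run counts and the success fraction.
#' @param runs A `dlm_runs` tibble.
#' @export
summarise_runs <- function(runs) {
  stopifnot(inherits(runs, "dlm_runs"))
  ok <- runs[runs$status == "ok", , drop = FALSE]
  tibble::tibble(
    n_runs = nrow(runs),
    n_failed = sum(runs$status != "ok"),
    success_fraction = nrow(ok) / nrow(runs),
    mape = mean(ok$mape, na.rm = TRUE),
    rmse = mean(ok$rmse),
    mae = mean(ok$mae),
    excluded_zero_hours = sum(ok$excluded_zero_hours)
  )
}

#' Accuracy over a grid of model settings
#'
#' Evaluates every combination of training length, lag order, and horizon by
#' rolling-origin simulation and reports per-cell mean MAPE, RMSE, and MAE —
#' the table by which model settings are compared and selected.
#'
#' By default the horizon columns share fits: for each (T, k) pair one
#' rolling evaluation is run at the largest horizon and each smaller horizon
#' is scored on the truncated prefix of the same simulations, making the
#' horizon comparison paired (a 144-h simulation contains its 48- and 96-h
#' prefixes) and three times cheaper. Set `share_fits = FALSE` for fully
#' independent runs per horizon (run counts then differ across horizons,
#' since shorter horizons admit later origins).
#'
#' @param series A [plant_series].
#' @param train_lengths,lag_orders,horizons Candidate settings; defaults are
#'   the 3 x 3 x 3 grid T in \{200, 500, 800\}, k in \{48, 72, 96\},
#'   H in \{48, 96, 144\}.
#' @param step Hours between forecast origins.
#' @param regressors Regressor set for every cell.
#' @param share_fits Share fits across horizon columns (default `TRUE`).
#' @return A tibble of class `dlm_grid`: one row per (T, k, H) cell with
#'   `mape`, `rmse`, `mae`, `n_runs`, `n_failed`, `digester_id`.
#' @export
grid_report <- function(series,
                        train_lengths = c(200L, 500L, 800L),
                        lag_orders = c(48L, 72L, 96L),
                        horizons = c(48L, 96L, 144L),
                        step = 24,
                        regressors = "solid_feed",
                        share_fits = TRUE) {
  stopifnot(is_plant_series(series))
  if (length(train_lengths) < 1 || length(lag_orders) < 1 || length(horizons) < 1) {
    abort_config("Each settings set must be non-empty.")
  }
  horizons <- sort(unique(as.integer(horizons)))
  cells <- tidyr::expand_grid(train_length = as.integer(train_lengths),
                              lag_order = as.integer(lag_orders))
  out <- purrr::pmap_dfr(cells, function(train_length, lag_order) {
    if (share_fits) {
      cfg <- dlm_config(lag_order = lag_order, train_length = train_length,
                        horizon = max(horizons), regressors = regressors)
      runs <- rolling_evaluate(series, cfg, step = step, keep_models = FALSE)
      purrr::map_dfr(horizons, function(H) {
        cbind_settings(truncated_summary(runs, H), train_length, lag_order, H)
      })
    } else {
      purrr::map_dfr(horizons, function(H) {
        cfg <- dlm_config(lag_order = lag_order, train_length = train_length,
                          horizon = H, regressors = regressors)
        runs <- rolling_evaluate(series, cfg, step = step, keep_models = FALSE)
        cbind_settings(summarise_runs(runs), train_length, lag_order, H)
      })
    }
  })
  out$digester_id <- attr(series, "digester_id") %||% "D1"
  tibble::new_tibble(out, class = "dlm_grid")
}

# Re-score every successful run on the first H hours of its simulation.
truncated_summary <- function(runs, H) {
  ok <- runs$status == "ok"
  rescored <- purrr::map_dfr(which(ok), function(i) {
    accuracy_metrics(runs$observed[[i]][seq_len(H)],
                     runs$simulated[[i]][seq_len(H)])
  })
  tibble::tibble(
    n_runs = nrow(runs),
    n_failed = sum(!ok),
    success_fraction = mean(ok),
    mape = mean(rescored$mape, na.rm = TRUE),
    rmse = mean(rescored$rmse),
    mae = mean(rescored$mae),
    excluded_zero_hours = sum(rescored$excluded_zero_hours)
  )
}

cbind_settings <- function(summary_row, train_length, lag_order, horizon) {
  dplyr::bind_cols(
    tibble::tibble(train_length = train_length, lag_order = lag_order,
                   horizon = horizon),
    summary_row
  )
}

#' @describeIn grid_report Wide, report-style layout: one row per (T, k),
#'   one column per horizon, for a chosen metric.
#' @param report A `dlm_grid`.
#' @param metric One of `"mape"`, `"rmse"`, `"mae"`.
#' @export
grid_wide <- function(report, metric = c("mape", "rmse", "mae")) {
  stopifnot(inherits(report, "dlm_grid"))
  metric <- match.arg(metric)
  report |>
    dplyr::select(dplyr::all_of(c("train_length", "lag_order", "horizon", metric))) |>
    tidyr::pivot_wider(names_from = "horizon",
                       values_from = dplyr::all_of(metric),
                       names_prefix = "H") |>
    dplyr::arrange(.data$train_length, .data$lag_order)
}

#' @describeIn grid_report Metric-versus-horizon lines per settings cell.
#' @param object A `dlm_grid`.
#' @param ... Unused.
#' @export
autoplot.dlm_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("mape", "rmse", "mae"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$horizon, y = .data$value,
    colour = factor(.data$train_length),
    linetype = factor(.data$lag_order)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "horizon H (h)", y = NULL,
                  colour = "T (obs)", linetype = "k (lags)")
}
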