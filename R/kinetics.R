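#' Pool fitted coefficients across rolling runs
#'
#' Collects the intercepts and per-lag coefficient vectors of every
#' successful run of a rolling evaluation into a coefficient ensemble — the
#' raw material for studying gas-formation kinetics: the lag-profile of the
#' coefficients traces how the gas from one kg of substrate is released over
#' the hours after feeding.
#'
#' @param runs A `dlm_runs` tibble from [rolling_evaluate()] with
#'   `keep_models = TRUE`, or a plain list of `biogas_dlm` fits. All fits
#'   must share the same lag order and regressor set.
#' @return An object of class `coef_ensemble`: per regressor a runs x (k+1)
#'   matrix of coefficients (m^3 kg^-1), the per-run intercepts (m^3 h^-1),
#'   the shared config, and the number of excluded (failed) runs.
#' @examples
#' sim <- generate_plant(plant_scenario(duration = 2000, seed = 11))
#' runs <- rolling_evaluate(sim$series,
#'                          dlm_config(train_length = 500, lag_order = 48,
#'                                     horizon = 48))
#' ens <- collect_coefficients(runs)
#' auc_yield(median_curve(ens), window = 48)
#' @export
collect_coefficients <- function(runs) {
  models <- if (inherits(runs, "dlm_runs")) {
    if (!"model" %in% names(runs)) {
      abort_config("Runs carry no models; rerun rolling_evaluate() with keep_models = TRUE.")
    }
    runs$model[runs$status == "ok"]
  } else if (is.list(runs) && !is.data.frame(runs)) {
    runs
  } else {
    abort_schema("`runs` must be a dlm_runs tibble or a list of fits.")
  }
  models <- models[!vapply(models, is.null, logical(1))]
  n_total <- if (inherits(runs, "dlm_runs")) nrow(runs) else length(runs)
  if (length(models) < 1) {
    abort_config("No successful runs to collect coefficients from.")
  }
  if (!all(vapply(models, inherits, logical(1), "biogas_dlm"))) {
    abort_schema("All elements must be fitted `biogas_dlm` models.")
  }
  k0 <- models[[1]]$config$lag_order
  regs0 <- models[[1]]$config$regressors
  same <- vapply(models, function(m) {
    m$config$lag_order == k0 && identical(m$config$regressors, regs0)
  }, logical(1))
  if (!all(same)) {
    abort_config("Heterogeneous configs: all runs must share lag order and regressor set.")
  }
  betas <- lapply(regs0, function(r) {
    do.call(rbind, lapply(models, function(m) unname(m$betas[[r]])))
  })
  names(betas) <- regs0
  structure(
    list(betas = betas,
         alpha = vapply(models, function(m) m$alpha, numeric(1)),
         config = models[[1]]$config,
         n_runs = length(models),
         n_excluded = n_total - length(models)),
    class = "coef_ensemble"
  )
}

#' @export
print.coef_ensemble <- function(x, ...) {
  cat(sprintf(
    "<coef_ensemble> %d runs (%d excluded), k = %d, regressors: %s\n  median intercept %.3f m3/h\n",
    x$n_runs, x$n_excluded, x$config$lag_order,
    paste(x$config$regressors, collapse = " + "), stats::median(x$alpha)
  ))
  invisible(x)
}

#' @describeIn collect_coefficients Per-lag coefficient quartiles for every
#'   regressor, as a tibble (`regressor`, `lag`, `q25`, `median`, `q75`,
#'   `mean`, `sd`, `n_runs`).
#' @param x A `coef_ensemble`.
#' @param ... Unused.
#' @export
tidy.coef_ensemble <- function(x, ...) {
  purrr::map_dfr(names(x$betas), function(r) {
    m <- x$betas[[r]]
    tibble::tibble(
      regressor = r,
      lag = 0:(ncol(m) - 1),
      q25 = apply(m, 2, stats::quantile, 0.25, names = FALSE),
      median = apply(m, 2, stats::median),
      q75 = apply(m, 2, stats::quantile, 0.75, names = FALSE),
      mean = colMeans(m),
      sd = apply(m, 2, stats::sd),
      n_runs = nrow(m)
    )
  })
}

#' Median gas-formation curve
#'
#' The lag-wise median of the ensemble coefficients for one regressor: the
#' central estimate of the specific gas-formation curve, in m^3 of biogas
#' per kg of substrate released in each hourly bin after feeding.
#'
#' @param ensemble A [collect_coefficients()] ensemble.
#' @param regressor Regressor whose curve to extract.
#' @return A tibble with columns `lag` (0..k) and `beta` (m^3 kg^-1).
#' @export
median_curve <- function(ensemble, regressor = "solid_feed") {
  stopifnot(inherits(ensemble, "coef_ensemble"))
  if (!regressor %in% names(ensemble$betas)) {
    abort_schema(sprintf("Regressor `%s` not in ensemble (has: %s).",
                         regressor, paste(names(ensemble$betas), collapse = ", ")))
  }
  m <- ensemble$betas[[regressor]]
  tibble::tibble(lag = 0:(ncol(m) - 1), beta = apply(m, 2, stats::median))
}

#' Cumulative specific biogas yield from a coefficient curve
#'
#' Integrates the gas-formation curve over the first `window` hourly lag
#' bins as a unit-width Riemann sum: each coefficient is already the m^3 of
#' gas per kg of substrate attributed to one hourly bin, so the specific
#' yield within the window is simply their sum. The returned cumulative
#' curve lets the fraction of total gas released by any hour be read off
#' (e.g. the share released within the first 12 h).
#'
#' The model intercept is deliberately not part of the yield: it absorbs the
#' baseline production from substrate fed before the lag window, i.e. a
#' residual amount of gas that cannot be attributed to the modelled
#' feedings.
#'
#' @param curve A tibble with columns `lag` and `beta` (from
#'   [median_curve()]) or a bare numeric vector of per-lag coefficients.
#' @param window Number of leading hourly bins to integrate (lags
#'   0..window-1).
#' @return An object of class `auc_yield`: `yield` (m^3 kg^-1 within
#'   `window` hours), `window`, and `cumulative`, a tibble with `lag`,
#'   `beta`, `cumulative` yield and `fraction` of the window total.
#' @export
auc_yield <- function(curve, window = NULL) {
  beta <- if (is.data.frame(curve)) {
    if (!all(c("lag", "beta") %in% names(curve))) {
      abort_schema("`curve` must have columns `lag` and `beta`.")
    }
    curve$beta[order(curve$lag)]
  } else if (is.numeric(curve)) {
    as.numeric(curve)
  } else {
    abort_schema("`curve` must be a tibble or numeric vector.")
  }
  if (is.null(window)) window <- length(beta)
  if (window < 1 || window > length(beta)) {
    abort_bounds(sprintf("`window` (%d) must be in 1..%d available lag bins.",
                         window, length(beta)))
  }
  b <- beta[seq_len(window)]
  cum <- cumsum(b)
  total <- cum[window]
  structure(
    list(yield = total,
         window = as.integer(window),
         cumulative = tibble::tibble(
           lag = 0:(window - 1),
           beta = b,
           cumulative = cum,
           fraction = if (total != 0) cum / total else rep(NA_real_, window)
         )),
    class = "auc_yield"
  )
}

#' @export
print.auc_yield <- function(x, ...) {
  cat(sprintf(
    "<auc_yield> %.4f m3 biogas per kg substrate within %d h\n",
    x$yield, x$window
  ))
  h12 <- min(12, x$window)
  cat(sprintf("  fraction released by hour %d: %.1f%%\n",
              h12, 100 * x$cumulative$fraction[h12]))
  cat("  (intercept excluded: residual gas from pre-window feeding is not attributed)\n")
  invisible(x)
}

#' Diagnostics for a secondary feeding regressor
#'
#' Summarises the ensemble coefficients of an additional regressor —
#' typically liquid manure — per lag: quartiles, a robust standard error of
#' the median, and whether the median is statistically indistinguishable
#' from zero. When the liquid substrate is dosed at near-constant intervals
#' and amounts its hourly series carries almost no information beyond a
#' constant, so its effect is absorbed into the intercept and the
#' coefficients fluctuate around zero along all lags.
#'
#' @param ensemble A [collect_coefficients()] ensemble fitted with the
#'   regressor.
#' @param regressor Name of the secondary regressor.
#' @return A tibble with one row per lag (`lag`, `q25`, `median`, `q75`,
#'   `sd`, `near_zero`) and attributes `fraction_negative_median`,
#'   `fraction_near_zero`, `n_runs`. `near_zero` flags lags whose median is
#'   within two ensemble standard deviations of zero — i.e. the centre of
#'   the coefficient's boxplot sits well inside its own spread. The
#'   ensemble's rolling fits share most of their training data, so the
#'   cross-run dispersion, not a standard error that assumes independent
#'   runs, is the honest scale of uncertainty.
#' @export
second_regressor_report <- function(ensemble, regressor = "liquid_feed") {
  stopifnot(inherits(ensemble, "coef_ensemble"))
  if (!regressor %in% names(ensemble$betas)) {
    abort_schema(sprintf("Regressor `%s` not in ensemble (has: %s).",
                         regressor, paste(names(ensemble$betas), collapse = ", ")))
  }
  m <- ensemble$betas[[regressor]]
  n <- nrow(m)
  med <- apply(m, 2, stats::median)
  spread <- apply(m, 2, stats::sd)
  out <- tibble::tibble(
    lag = 0:(ncol(m) - 1),
    q25 = apply(m, 2, stats::quantile, 0.25, names = FALSE),
    median = med,
    q75 = apply(m, 2, stats::quantile, 0.75, names = FALSE),
    sd = spread,
    near_zero = abs(med) <= 2 * spread
  )
  tibble::new_tibble(out,
                     fraction_negative_median = mean(med < 0),
                     fraction_near_zero = mean(out$near_zero),
                     n_runs = n,
                     class = "second_regressor_report")
}

#' @describeIn collect_coefficients Box-and-whisker style view of the
#'   coefficient distribution per lag with the median curve overlaid.
#' @param object A `coef_ensemble`.
#' @export
autoplot.coef_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey75") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$regressor), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "lag (h after feeding)",
                  y = expression(beta ~ (m^3 ~ kg^-1)),
                  title = "Coefficient distribution across rolling fits",
                  subtitle = "ribbon: interquartile range; red: median gas-formation curve")
}
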