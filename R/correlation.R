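#' Cross-correlation screening of feeding against biogas production
#'
#' Computes the sample cross-correlation between a feeding regressor and the
#' biogas production for lags `-max_lag ... +max_lag`, the screening step that
#' justifies using lagged feeding as a predictor. A positive lag `h` means
#' the regressor leads the response: the value reported at lag `h` is the
#' correlation between `x` at time `t - h` and `y` at time `t`, matching how
#' past feeding enters the distributed-lag model.
#'
#' The estimator is the conventional one: cross-covariances are normalised by
#' the full-sample (biased, divide-by-n) standard deviations of the two
#' series, as computed by [stats::ccf()].
#'
#' @param data A data frame holding both series, typically a [plant_series].
#' @param x,y Column names of the regressor and response series.
#' @param max_lag Maximum lag, in hours, on either side.
#' @return A tibble of class `ccf_tbl` with columns `lag`, `correlation`, and
#'   attributes `n` (paired observations) and `conf_bound` (the two-sided
#'   white-noise 95% bound `qnorm(0.975)/sqrt(n)`).
#' @examples
#' sim <- generate_plant(plant_scenario(duration = 24 * 90, seed = 7))
#' cc <- cross_correlate(sim$series, max_lag = 48)
#' significant_lags(cc)
#' @export
cross_correlate <- function(data, x = "solid_feed", y = "biogas", max_lag = 48) {
  xv <- pull_numeric(data, x)
  yv <- pull_numeric(data, y)
  n <- length(xv)
  if (length(yv) != n) {
    abort_schema("`x` and `y` series must have equal length.")
  }
  if (max_lag < 1 || max_lag >= n - 2) {
    abort_bounds(sprintf("`max_lag` (%d) must be in [1, n - 3] for n = %d.",
                         max_lag, n))
  }
  if (stats::var(xv) == 0 || stats::var(yv) == 0) {
    abort_degenerate("Zero-variance input series: cross-correlation undefined.")
  }
  cc <- stats::ccf(xv, yv, lag.max = max_lag, plot = FALSE, demean = TRUE)
  # stats::ccf reports cor(x[t + lag], y[t]); our convention indexes by how
  # far x leads y, i.e. cor(x[t - h], y[t]), so the lag axis is negated.
  lags <- -rev(as.vector(cc$lag))
  vals <- rev(as.vector(cc$acf))
  tibble::new_tibble(
    tibble::tibble(lag = as.integer(lags), correlation = vals),
    n = n,
    conf_bound = stats::qnorm(0.975) / sqrt(n),
    class = "ccf_tbl"
  )
}

#' Lags with correlation beyond the white-noise bound
#'
#' Filters a [cross_correlate()] result down to the lags whose absolute
#' correlation exceeds the two-sided 95% white-noise bound, annotated by
#' sign.
#'
#' @param result A `ccf_tbl` from [cross_correlate()].
#' @return A tibble with columns `lag`, `correlation`, `sign`
#'   (`"positive"`/`"negative"`), ordered by decreasing absolute correlation.
#' @export
significant_lags <- function(result) {
  stopifnot(inherits(result, "ccf_tbl"))
  bound <- attr(result, "conf_bound")
  out <- result[abs(result$correlation) > bound, , drop = FALSE]
  out <- tibble::as_tibble(out)
  out$sign <- ifelse(out$correlation >= 0, "positive", "negative")
  out[order(-abs(out$correlation)), , drop = FALSE]
}

#' @export
print.ccf_tbl <- function(x, ...) {
  cat(sprintf("# Cross-correlation over lags %d..%d (n = %d, 95%% bound = %.4f)\n",
              min(x$lag), max(x$lag), attr(x, "n"), attr(x, "conf_bound")))
  NextMethod()
}

#' @describeIn cross_correlate Stem plot of the cross-correlation function
#'   with the white-noise significance band.
#' @param object A `ccf_tbl`.
#' @param ... Unused.
#' @export
autoplot.ccf_tbl <- function(object, ...) {
  bound <- attr(object, "conf_bound")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$correlation)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(-bound, bound),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::labs(x = "lag (h, positive = feeding leads biogas)",
                  y = "cross-correlation")
}

pull_numeric <- function(data, col) {
  if (is.numeric(data) && is.null(dim(data))) return(as.numeric(data))
  if (!is.data.frame(data)) abort_schema("`data` must be a data frame.")
  if (!col %in% names(data)) {
    abort_schema(sprintf("Column `%s` not found.", col))
  }
  v <- data[[col]]
  if (!is.numeric(v)) abort_schema(sprintf("Column `%s` must be numeric.", col))
  as.numeric(v)
}
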