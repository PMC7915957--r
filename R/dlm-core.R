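#' Model settings for the distributed-lag biogas model
#'
#' Bundles the settings of the self-learning distributed-lag regression:
#' the lag order k (how many past hourly feeding values enter as predictors),
#' the training length T (how many most-recent observations the model is
#' refit on), the simulation horizon H, the regressor set, and whether
#' simulated production is clamped at zero.
#'
#' The candidate values studied for full-scale digesters are
#' T in \{200, 500, 800\} h, k in \{48, 72, 96\} lags, and
#' H in \{48, 96, 144\} h; T = 500 with k = 48 is the usual default.
#'
#' @param lag_order Lag order k (hours). `0` fits a plain same-hour
#'   regression.
#' @param train_length Training period T in hourly observations; must exceed
#'   the number of fitted parameters, `1 + (lag_order + 1) * n_regressors`.
#' @param horizon Simulation horizon H in hours.
#' @param regressors Ordered character vector of regressor columns;
#'   `"solid_feed"` alone, or `c("solid_feed", "liquid_feed")`.
#' @param clamp_nonnegative If `TRUE` (default) simulated production is
#'   truncated at zero after evaluation of the linear predictor. Coefficient
#'   analysis never uses the clamp.
#' @return A list of class `dlm_config`.
#' @export
dlm_config <- function(lag_order = 48,
                       train_length = 500,
                       horizon = 48,
                       regressors = "solid_feed",
                       clamp_nonnegative = TRUE) {
  if (lag_order < 0) abort_config("`lag_order` must be >= 0.")
  if (horizon < 1) abort_config("`horizon` must be >= 1.")
  if (length(regressors) < 1) abort_config("At least one regressor is required.")
  if (anyDuplicated(regressors)) abort_config("Duplicate regressor names.")
  n_par <- 1 + (lag_order + 1) * length(regressors)
  if (train_length <= n_par) {
    abort_config(sprintf(
      "`train_length` (%d) must exceed the %d fitted parameters.",
      train_length, n_par
    ))
  }
  structure(
    list(lag_order = as.integer(lag_order),
         train_length = as.integer(train_length),
         horizon = as.integer(horizon),
         regressors = regressors,
         clamp_nonnegative = isTRUE(clamp_nonnegative)),
    class = "dlm_config"
  )
}

#' @export
print.dlm_config <- function(x, ...) {
  cat(sprintf(
    "<dlm_config> k = %d lags, T = %d obs, H = %d h, regressors: %s, clamp: %s\n",
    x$lag_order, x$train_length, x$horizon,
    paste(x$regressors, collapse = " + "), x$clamp_nonnegative
  ))
  invisible(x)
}

#' Build the lagged design matrix
#'
#' Assembles the response vector and design matrix of the distributed-lag
#' regression
#' \deqn{Y_t = \alpha + \beta_0 X_t + \beta_1 X_{t-1} + \dots + \beta_k X_{t-k} + \varepsilon_t}
#' for the T training rows ending at `train_end`. Every lagged value is an
#' actually observed measurement: the window must be preceded by k warm-up
#' rows, and no implicit zero-padding ever occurs. Columns are ordered
#' deterministically: intercept first, then each regressor in config order
#' with lags ascending 0..k.
#'
#' @param series A [plant_series].
#' @param config A [dlm_config].
#' @param train_end End of the training window: integer row index or
#'   timestamp. Defaults to the last row.
#' @return A list of class `dlm_design` with elements `response` (length T),
#'   `matrix` (T x (1 + sum(k+1) per regressor)), `config`, `train_end`.
#' @export
build_design <- function(series, config, train_end = nrow(series)) {
  stopifnot(is_plant_series(series), inherits(config, "dlm_config"))
  k <- config$lag_order
  T_len <- config$train_length
  absent <- setdiff(config$regressors, names(series))
  if (length(absent) > 0) {
    abort_schema(sprintf("Regressor%s absent from series: %s.",
                         if (length(absent) > 1) "s" else "",
                         paste0("`", absent, "`", collapse = ", ")))
  }
  i_end <- resolve_index(series, train_end)
  i_first <- i_end - T_len + 1
  if (i_first - k < 1) {
    abort_bounds(sprintf(
      "Insufficient warm-up history: training window of %d rows ending at row %d needs %d leading lag rows, but only %d rows precede it.",
      T_len, i_end, k, i_first - 1
    ))
  }
  rows <- i_first:i_end
  blocks <- lapply(config$regressors, function(r) {
    v <- series[[r]]
    m <- vapply(0:k, function(j) v[rows - j], numeric(T_len))
    colnames(m) <- paste0(r, "_lag", 0:k)
    m
  })
  X <- cbind(`(Intercept)` = rep(1, T_len), do.call(cbind, blocks))
  structure(
    list(response = series$biogas[rows],
         matrix = X,
         config = config,
         train_end = series$timestamp[i_end]),
    class = "dlm_design"
  )
}

#' Fit the distributed-lag model by ordinary least squares
#'
#' Solves the least-squares problem of a [build_design()] design by QR
#' decomposition (no explicit inverse). A rank-deficient design — e.g. a
#' window with no feeding at all, or an exactly constant liquid dosing that
#' is collinear with the intercept — raises a singular-design error naming
#' the offending columns; columns are never silently dropped.
#'
#' @param design A `dlm_design`, or a [plant_series] (in which case `config`
#'   and `train_end` are forwarded to [build_design()]).
#' @param config,train_end Used only when `design` is a plant series.
#' @return An object of class `biogas_dlm`: intercept `alpha` (m^3 h^-1),
#'   per-regressor coefficient vectors `betas` (m^3 kg^-1, lags 0..k),
#'   `residuals`, `fitted`, `sigma`, `r.squared`, `config`, `train_end`.
#' @examples
#' sim <- generate_plant(plant_scenario(duration = 1200, seed = 1))
#' fit <- fit_dlm(sim$series, dlm_config(train_length = 500, lag_order = 48))
#' glance(fit)
#' @export
fit_dlm <- function(design, config = NULL, train_end = NULL) {
  if (is_plant_series(design)) {
    if (is.null(config)) abort_config("`config` is required when fitting a plant series.")
    if (is.null(train_end)) train_end <- nrow(design)
    design <- build_design(design, config, train_end)
  }
  stopifnot(inherits(design, "dlm_design"))
  X <- design$matrix
  y <- design$response
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    abort_bounds(sprintf("Design has %d rows for %d parameters; need rows > columns.", n, p))
  }
  qd <- qr(X, tol = 1e-10)
  if (qd$rank < p) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1):p]]
    abort_singular(sprintf(
      "Singular design (rank %d < %d); offending column%s: %s.",
      qd$rank, p, if (length(bad) > 1) "s" else "",
      paste0("`", bad, "`", collapse = ", ")
    ))
  }
  coefs <- qr.coef(qd, y)
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  k <- design$config$lag_order
  betas <- lapply(design$config$regressors, function(r) {
    b <- coefs[paste0(r, "_lag", 0:k)]
    names(b) <- paste0("lag", 0:k)
    b
  })
  names(betas) <- design$config$regressors
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(alpha = unname(coefs[["(Intercept)"]]),
         betas = betas,
         coefficients = coefs,
         residuals = resid,
         fitted = fitted,
         sigma = sqrt(rss / (n - p)),
         r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
         nobs = n,
         df.residual = n - p,
         config = design$config,
         train_end = design$train_end),
    class = "biogas_dlm"
  )
}

#' @export
print.biogas_dlm <- function(x, ...) {
  cat(sprintf(
    "<biogas_dlm> k = %d, T = %d, regressors: %s\n  alpha = %.3f m3/h, sigma = %.3f, R^2 = %.4f, trained to %s\n",
    x$config$lag_order, x$nobs, paste(x$config$regressors, collapse = " + "),
    x$alpha, x$sigma, x$r.squared, format_hour_stamp(x$train_end)
  ))
  invisible(x)
}

#' Simulate biogas production from a planned feeding schedule
#'
#' Evaluates the fitted distributed-lag model over H future hours:
#' \eqn{\hat y(t) = \alpha + \sum_r \sum_{j=0}^{k} \beta_{r,j} X_r(t-j)},
#' where future X values come from the planned schedule and the most recent
#' k observed values supply the lagged terms that reach back before the
#' simulation start. The model contains no autoregressive response terms, so
#' multi-step simulation needs no recursion on its own output.
#'
#' @param model A fitted `biogas_dlm`.
#' @param planned_feed Future feeding: a data frame with one column per model
#'   regressor and H rows, or a numeric vector for a single-regressor model.
#' @param recent_history The last >= k observed feeding values per regressor
#'   (same shape rules as `planned_feed`); only the final k rows are used.
#'   May be omitted when k = 0.
#' @param clamp Override the config's `clamp_nonnegative` flag; simulated
#'   production is physically non-negative, so the clamp defaults to on.
#' @return A tibble with columns `hour` (1..H) and `simulated` (m^3 h^-1).
#' @export
simulate_biogas <- function(model, planned_feed, recent_history = NULL,
                            clamp = NULL) {
  stopifnot(inherits(model, "biogas_dlm"))
  regs <- model$config$regressors
  k <- model$config$lag_order
  planned <- as_regressor_frame(planned_feed, regs, "planned_feed")
  H <- nrow(planned)
  if (H < 1) abort_bounds("`planned_feed` must contain at least one hour.")
  if (k > 0) {
    hist <- as_regressor_frame(recent_history, regs, "recent_history")
    if (nrow(hist) < k) {
      abort_bounds(sprintf(
        "`recent_history` provides %d rows but lag order k = %d requires at least k.",
        nrow(hist), k
      ))
    }
  }
  yhat <- rep(model$alpha, H)
  for (r in regs) {
    beta <- unname(model$betas[[r]])
    full <- c(if (k > 0) utils::tail(hist[[r]], k) else numeric(0), planned[[r]])
    for (t in seq_len(H)) {
      yhat[t] <- yhat[t] + sum(beta * full[(k + t):t])
    }
  }
  if (is.null(clamp)) clamp <- model$config$clamp_nonnegative
  if (clamp) yhat <- pmax(yhat, 0)
  tibble::tibble(hour = seq_len(H), simulated = yhat)
}

#' @export
predict.biogas_dlm <- function(object, planned_feed, recent_history = NULL,
                               clamp = NULL, ...) {
  simulate_biogas(object, planned_feed, recent_history, clamp)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_dlm Coefficients as a tibble: one row per term with
#'   `regressor`, `lag` (`NA` for the intercept), `estimate`.
#' @param x A `biogas_dlm`.
#' @param ... Unused.
#' @export
tidy.biogas_dlm <- function(x, ...) {
  k <- x$config$lag_order
  rows <- purrr::map_dfr(x$config$regressors, function(r) {
    tibble::tibble(term = paste0(r, "_lag", 0:k),
                   regressor = r, lag = 0:k,
                   estimate = unname(x$betas[[r]]))
  })
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", regressor = NA_character_,
                   lag = NA_integer_, estimate = x$alpha),
    rows
  )
}

#' @describeIn fit_dlm One-row fit summary: `r.squared`, `sigma`, `nobs`,
#'   `df.residual`, `lag_order`, `n_regressors`.
#' @export
glance.biogas_dlm <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared,
    sigma = x$sigma,
    nobs = x$nobs,
    df.residual = x$df.residual,
    lag_order = x$config$lag_order,
    n_regressors = length(x$config$regressors)
  )
}

#' @describeIn fit_dlm Coefficient-versus-lag curve of the fitted model.
#' @param object A `biogas_dlm`.
#' @export
autoplot.biogas_dlm <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$lag), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$regressor), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "lag (h)", y = expression(beta ~ (m^3 ~ kg^-1)))
}

as_regressor_frame <- function(x, regs, what) {
  if (is.null(x)) {
    abort_bounds(sprintf("`%s` is required when the lag order is positive.", what))
  }
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(regs) != 1) {
      abort_schema(sprintf(
        "`%s` given as a bare vector but the model has %d regressors (%s).",
        what, length(regs), paste(regs, collapse = ", ")
      ))
    }
    out <- tibble::tibble(value = as.numeric(x))
    names(out) <- regs
    return(out)
  }
  if (!is.data.frame(x)) {
    abort_schema(sprintf("`%s` must be a data frame or numeric vector.", what))
  }
  absent <- setdiff(regs, names(x))
  if (length(absent) > 0) {
    abort_schema(sprintf("`%s` lacks regressor column%s: %s.", what,
                         if (length(absent) > 1) "s" else "",
                         paste0("`", absent, "`", collapse = ", ")))
  }
  tibble::as_tibble(x)[regs]
}
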