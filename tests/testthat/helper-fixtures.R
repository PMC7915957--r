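# Shared fixture builders: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

hourly_stamps <- function(n, start = "2018-01-01 00:00:00") {
  seq(as.POSIXct(start, tz = "UTC"), by = "hour", length.out = n)
}

# Minimal hand-rolled series: constant biogas unless supplied.
make_series <- function(n, solid = NULL, biogas = NULL, liquid = NULL,
                        digester_id = "T1") {
  d <- tibble::tibble(
    timestamp = hourly_stamps(n),
    solid_feed = solid %||% rep(c(0, 0, 800, 0), length.out = n),
    biogas = biogas %||% rep(65, n)
  )
  if (!is.null(liquid)) d$liquid_feed <- liquid
  plant_series(d, digester_id = digester_id)
}

# Independent double-loop cross-correlation estimator (full-sample, biased
# normalisation; positive lag h pairs x[t - h] with y[t]).
brute_ccf <- function(x, y, max_lag) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean((x - mx)^2)); sy <- sqrt(mean((y - my)^2))
  vapply(-max_lag:max_lag, function(h) {
    s <- 0
    for (t in seq_len(n)) {
      tx <- t - h
      if (tx >= 1 && tx <= n) s <- s + (x[tx] - mx) * (y[t] - my)
    }
    s / n / (sx * sy)
  }, numeric(1))
}

# Quick noiseless oracle scenario.
noiseless_scenario <- function(duration, seed, ...) {
  plant_scenario(duration = duration, noise_sd = 0, downtime = NULL,
                 seed = seed, ...)
}
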