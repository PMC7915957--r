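#' Hourly digester time series
#'
#' A `plant_series` is a tibble with one row per hour holding the measured
#' solid-substrate feeding (kg h^-1), optionally the liquid-substrate feeding
#' (kg h^-1), and the biogas production at standard conditions (m^3 h^-1) of a
#' single digester. Timestamps must be strictly increasing with exact 1-hour
#' spacing and all measurements must be non-negative; missing values are not
#' allowed in a validated series (see the `repair` argument of
#' [read_plant_series()]).
#'
#' Timestamps are carried as labels only: every model operation in the package
#' works on the integer hour index, so calendar effects play no role.
#'
#' @param data A data frame with columns `timestamp` (`POSIXct` or ISO-8601
#'   character), `solid_feed`, `biogas`, and optionally `liquid_feed`.
#' @param digester_id Label identifying the digester the series belongs to.
#' @return A tibble of class `plant_series` with attribute `digester_id`.
#' @examples
#' ts0 <- seq(as.POSIXct("2018-01-01 00:00:00", tz = "UTC"),
#'            by = "hour", length.out = 24)
#' ps <- plant_series(data.frame(
#'   timestamp = ts0,
#'   solid_feed = c(rep(0, 7), 900, rep(0, 15), 500),
#'   biogas = rep(65, 24)
#' ))
#' nrow(ps)
#' @export
plant_series <- function(data, digester_id = "D1") {
  if (!is.data.frame(data)) {
    abort_schema("`data` must be a data frame.")
  }
  data <- tibble::as_tibble(data)
  required <- c("timestamp", "solid_feed", "biogas")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "Missing required column%s: %s.",
      if (length(missing_cols) > 1) "s" else "",
      paste0("`", missing_cols, "`", collapse = ", ")
    ))
  }
  if (is.character(data$timestamp)) {
    data$timestamp <- parse_hour_stamp(data$timestamp)
  }
  if (!inherits(data$timestamp, "POSIXct")) {
    abort_schema("`timestamp` must be POSIXct or ISO-8601 character.")
  }
  attr(data$timestamp, "tzone") <- "UTC"
  keep <- intersect(c("timestamp", "solid_feed", "liquid_feed", "biogas"),
                    names(data))
  data <- data[keep]
  data <- data[order(data$timestamp), , drop = FALSE]
  out <- tibble::new_tibble(data, digester_id = digester_id,
                            class = "plant_series")
  validate_plant_series(out)
}

#' @rdname plant_series
#' @param x Object to test or validate.
#' @export
is_plant_series <- function(x) inherits(x, "plant_series")

#' @rdname plant_series
#' @export
validate_plant_series <- function(x) {
  stamps <- x$timestamp
  n <- length(stamps)
  if (n == 0) abort_validation("A plant series must contain at least one hour.")
  if (anyDuplicated(stamps) > 0) {
    dup <- stamps[duplicated(stamps)][1]
    abort_validation(sprintf("Duplicate timestamp: %s.", format_hour_stamp(dup)))
  }
  if (n > 1) {
    gaps <- diff(as.numeric(stamps))
    bad <- which(abs(gaps - 3600) > 1e-6)
    if (length(bad) > 0) {
      i <- bad[1]
      abort_gap(sprintf(
        "Non-uniform hourly spacing: %s -> %s (expected 1 h).",
        format_hour_stamp(stamps[i]), format_hour_stamp(stamps[i + 1])
      ))
    }
  }
  for (col in intersect(c("solid_feed", "liquid_feed", "biogas"), names(x))) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      abort_schema(sprintf("Column `%s` must be numeric.", col))
    }
    if (anyNA(v)) {
      abort_validation(sprintf(
        "Column `%s` contains missing values (first at row %d); use `repair = TRUE` in read_plant_series() to impute explicitly.",
        col, which(is.na(v))[1]
      ))
    }
    if (any(v < 0)) {
      abort_validation(sprintf(
        "Column `%s` contains negative values (first at row %d).",
        col, which(v < 0)[1]
      ))
    }
  }
  x
}

#' @export
print.plant_series <- function(x, ...) {
  cat(sprintf(
    "# A plant_series: %d hourly observations, digester %s\n",
    nrow(x), attr(x, "digester_id")
  ))
  cat(sprintf(
    "# %s -> %s%s\n",
    format_hour_stamp(x$timestamp[1]),
    format_hour_stamp(x$timestamp[nrow(x)]),
    if ("liquid_feed" %in% names(x)) ", with liquid feed" else ""
  ))
  NextMethod()
}

#' Read an hourly plant series from CSV
#'
#' Reads a comma-separated file with a header row, an ISO-8601 timestamp
#' column, at least one feeding column, and a biogas-production column, and
#' returns a validated [plant_series]. Rows are sorted by time; duplicate
#' timestamps and hourly gaps are rejected.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping internal names
#'   (`timestamp`, `solid_feed`, `liquid_feed`, `biogas`) to the column names
#'   used in the file. Defaults to the names written by [write_plant_series()].
#' @param digester_id Label for the digester; defaults to the file name.
#' @param repair If `TRUE`, missing feeding values are forward-filled (a
#'   feeding that was not logged is taken as "no feeding since the last
#'   record") and missing biogas values are linearly interpolated; every
#'   repair is reported via a message. Default `FALSE`: missing values are an
#'   error, because silent imputation would corrupt downstream fits.
#' @return A [plant_series].
#' @export
read_plant_series <- function(path,
                              column_map = NULL,
                              digester_id = NULL,
                              repair = FALSE) {
  default_map <- c(timestamp = "timestamp", solid_feed = "solid_feed_kg_h",
                   liquid_feed = "liquid_feed_kg_h", biogas = "biogas_m3_h")
  map <- default_map
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(default_map))
    if (length(unknown) > 0) {
      abort_schema(sprintf("Unknown column_map entries: %s.",
                           paste(unknown, collapse = ", ")))
    }
    map[names(column_map)] <- column_map
  }
  # columns come in as text and are converted via strtod so that values
  # written at %.17g round-trip bit-exactly
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("timestamp", "solid_feed", "biogas")
  for (field in required) {
    if (!map[[field]] %in% names(raw)) {
      abort_schema(sprintf("Column `%s` (for %s) not found in %s.",
                           map[[field]], field, path))
    }
  }
  out <- tibble::tibble(
    timestamp = raw[[map[["timestamp"]]]],
    solid_feed = as.numeric(raw[[map[["solid_feed"]]]]),
    biogas = as.numeric(raw[[map[["biogas"]]]])
  )
  if (map[["liquid_feed"]] %in% names(raw)) {
    out$liquid_feed <- as.numeric(raw[[map[["liquid_feed"]]]])
    out <- out[c("timestamp", "solid_feed", "liquid_feed", "biogas")]
  }
  if (is.character(out$timestamp)) {
    out$timestamp <- parse_hour_stamp(out$timestamp)
  }
  if (repair) {
    out <- out[order(out$timestamp), , drop = FALSE]
    for (col in intersect(c("solid_feed", "liquid_feed"), names(out))) {
      n_miss <- sum(is.na(out[[col]]))
      if (n_miss > 0) {
        out[[col]] <- forward_fill(out[[col]])
        message(sprintf("repair: forward-filled %d missing `%s` values", n_miss, col))
      }
    }
    n_miss <- sum(is.na(out$biogas))
    if (n_miss > 0) {
      out$biogas <- linear_interp(out$biogas)
      message(sprintf("repair: linearly interpolated %d missing `biogas` values", n_miss))
    }
  }
  if (is.null(digester_id)) {
    digester_id <- sub("\\.[^.]*$", "", basename(path))
  }
  plant_series(out, digester_id = digester_id)
}

#' Write an hourly plant series to CSV
#'
#' Writes one row per hour with columns `timestamp` (format
#' `YYYY-MM-DDTHH:00:00`), `solid_feed_kg_h`, `liquid_feed_kg_h` (only when
#' the series carries a liquid regressor), and `biogas_m3_h`. Values
#' round-trip through [read_plant_series()] at full double precision.
#'
#' @param series A [plant_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plant_series <- function(series, path) {
  stopifnot(is_plant_series(series))
  # %.17g guarantees bit-exact double round-trips through the text file
  out <- tibble::tibble(
    timestamp = format_hour_stamp(series$timestamp),
    solid_feed_kg_h = sprintf("%.17g", series$solid_feed)
  )
  if ("liquid_feed" %in% names(series)) {
    out$liquid_feed_kg_h <- sprintf("%.17g", series$liquid_feed)
  }
  out$biogas_m3_h <- sprintf("%.17g", series$biogas)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Extract a training window from a plant series
#'
#' Returns the sub-series of `length` hourly observations ending at `end`,
#' preceded by `warmup` additional leading observations so that all lagged
#' regressor values exist for every row of the window proper. A window for a
#' distributed-lag fit with training length T and lag order k is requested as
#' `slice_window(series, end, length = T, warmup = k)` and always has exactly
#' `T + k` rows (or errors).
#'
#' @param series A [plant_series].
#' @param end End of the window: an integer row index, or a timestamp
#'   (`POSIXct` or ISO-8601 character) present in the series.
#' @param length Number of observations in the window proper.
#' @param warmup Number of extra leading observations (typically the lag
#'   order k).
#' @return A [plant_series] of `length + warmup` rows.
#' @export
slice_window <- function(series, end, length, warmup = 0) {
  stopifnot(is_plant_series(series))
  if (length < 1 || warmup < 0) {
    abort_bounds("`length` must be >= 1 and `warmup` >= 0.")
  }
  i_end <- resolve_index(series, end)
  i_start <- i_end - length - warmup + 1
  if (i_start < 1) {
    abort_bounds(sprintf(
      "Insufficient history: window of %d + %d warm-up rows ending at %s needs %d rows, series provides %d before that point.",
      length, warmup, format_hour_stamp(series$timestamp[i_end]),
      length + warmup, i_end
    ))
  }
  out <- series[i_start:i_end, , drop = FALSE]
  tibble::new_tibble(out, digester_id = attr(series, "digester_id"),
                     class = "plant_series")
}

# -- internal helpers ---------------------------------------------------------

resolve_index <- function(series, at) {
  if (is.numeric(at) && length(at) == 1 && at == as.integer(at)) {
    i <- as.integer(at)
    if (i < 1 || i > nrow(series)) {
      abort_bounds(sprintf("Index %d outside series of length %d.", i, nrow(series)))
    }
    return(i)
  }
  if (is.character(at)) at <- parse_hour_stamp(at)
  if (inherits(at, "POSIXct")) {
    i <- match(as.numeric(at), as.numeric(series$timestamp))
    if (is.na(i)) {
      abort_bounds(sprintf("Timestamp %s not present in series.", format_hour_stamp(at)))
    }
    return(i)
  }
  abort_schema("`end` must be an integer index or a timestamp.")
}

parse_hour_stamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  fallback <- is.na(out) & !is.na(x)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], tz = "UTC")
  }
  if (anyNA(out[!is.na(x)])) {
    abort_schema(sprintf("Unparseable timestamp: %s.", x[is.na(out)][1]))
  }
  out
}

format_hour_stamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

forward_fill <- function(v) {
  idx <- cumsum(!is.na(v))
  filled <- c(NA_real_, v[!is.na(v)])[idx + 1]
  filled[is.na(filled)] <- 0  # leading gap: no feeding recorded yet
  filled
}

linear_interp <- function(v) {
  if (!anyNA(v)) return(v)
  stats::approx(seq_along(v), v, xout = seq_along(v), rule = 2)$y
}

regressor_columns <- function(series) {
  intersect(c("solid_feed", "liquid_feed"), names(series))
}

abort_schema <- function(msg) rlang::abort(msg, class = "biogasdlm_error_schema")
abort_gap <- function(msg) rlang::abort(msg, class = "biogasdlm_error_gap")
abort_validation <- function(msg) rlang::abort(msg, class = "biogasdlm_error_validation")
abort_bounds <- function(msg) rlang::abort(msg, class = "biogasdlm_error_bounds")
abort_singular <- function(msg) rlang::abort(msg, class = "biogasdlm_error_singular")
abort_degenerate <- function(msg) rlang::abort(msg, class = "biogasdlm_error_degenerate")
abort_config <- function(msg) rlang::abort(msg, class = "biogasdlm_error_config")
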