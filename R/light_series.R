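#' luxmetrics: light-exposure time series for wearable loggers
#'
#' Import, preprocessing and a metric engine for personal light-exposure
#' data recorded by wearable light loggers and dosimeters.
#'
#' @importFrom rlang .data abort %||%
#' @importFrom stats quantile sd rnorm
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

#' Construct a light-exposure time series
#'
#' A `light_series` holds one participant's (or one device deployment's)
#' ordered light measurements: a timezone-aware timestamp per epoch plus one
#' or more numeric light channels (illuminance or melanopic EDI, in lux).
#' A timestamp marks the *start* of its epoch, so every duration downstream
#' is a whole multiple of the sampling interval.
#'
#' @param datetime `POSIXct` vector, strictly increasing, with a timezone.
#' @param values numeric vector, or a data frame / named list of numeric
#'   vectors (one per channel). `NA` marks an explicitly missing epoch.
#' @param id participant/device identifier (length-1 character).
#' @param channel channel name used when `values` is a bare vector.
#' @param epoch sampling interval in seconds; inferred as the modal
#'   successive timestamp difference when `NULL` (ties resolve to the
#'   smaller interval). Must be given for series with fewer than 2 rows.
#' @return A `light_series`: a tibble with a `Datetime` column and one
#'   column per channel, carrying `id`, `epoch` and `channels` attributes.
#' @examples
#' t0 <- as.POSIXct("2024-03-01 08:00:00", tz = "UTC")
#' light_series(t0 + 60 * (0:9), c(0, 0, 250, 800, 900, 850, 400, 120, 0, 0))
#' @export
light_series <- function(datetime, values, id = "P1", channel = "lux",
                         epoch = NULL) {
  if (!inherits(datetime, "POSIXct")) {
    abort("`datetime` must be POSIXct")
  }
  if (is.numeric(values)) {
    values <- stats::setNames(list(values), channel)
  }
  values <- tibble::as_tibble(as.list(values))
  chans <- names(values)[vapply(values, is.numeric, logical(1))]
  dat <- tibble::tibble(Datetime = datetime)
  dat <- dplyr::bind_cols(dat, values)
  if (is.null(epoch)) {
    epoch <- if (length(datetime) >= 2) dominant_epoch(datetime) else NA_real_
  }
  out <- new_light_series(dat, id = id, epoch = as.numeric(epoch),
                          channels = chans)
  validate_light_series(out)
}

new_light_series <- function(data, id, epoch, channels) {
  structure(
    tibble::as_tibble(data),
    id = id, epoch = epoch, channels = channels,
    class = c("light_series", class(tibble::tibble()))
  )
}

# rebuild a light_series around new row data, keeping identity metadata
ls_rebuild <- function(x, data, epoch = series_epoch(x),
                       channels = intersect(series_channels(x), names(data))) {
  new_light_series(data, id = series_id(x), epoch = epoch, channels = channels)
}

validate_light_series <- function(x) {
  t <- x$Datetime
  if (anyNA(t)) abort("timestamps must not be missing")
  if (length(t) >= 2 && any(diff(as.numeric(t)) <= 0)) {
    abort("timestamps must be strictly increasing within an id")
  }
  for (ch in series_channels(x)) {
    v <- x[[ch]]
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("channel '%s' contains negative light values", ch))
    }
  }
  ep <- series_epoch(x)
  if (!is.na(ep) && ep <= 0) abort("epoch must be positive")
  x
}

#' Accessors for light_series metadata
#'
#' @param x a `light_series`.
#' @return `series_id()` the identifier, `series_epoch()` the sampling
#'   interval in seconds, `series_channels()` the light-channel column
#'   names, `series_tz()` the IANA timezone of the timestamps.
#' @export
series_id <- function(x) attr(x, "id")

#' @rdname series_id
#' @export
series_epoch <- function(x) attr(x, "epoch")

#' @rdname series_id
#' @export
series_channels <- function(x) attr(x, "channels")

#' @rdname series_id
#' @export
series_tz <- function(x) {
  tz <- attr(x$Datetime, "tzone")
  if (is.null(tz) || identical(tz, "")) "UTC" else tz[1]
}

# first light channel, or a named one, as a numeric vector
series_values <- function(x, channel = NULL) {
  channel <- channel %||% series_channels(x)[1]
  if (is.null(channel) || is.na(channel) || !channel %in% names(x)) {
    abort("series has no such light channel")
  }
  x[[channel]]
}

#' @export
print.light_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<light_series> id: %s | %d epochs of %s s | tz: %s\n",
              series_id(x), n,
              format(series_epoch(x)), series_tz(x)))
  if (n > 0) {
    cat(sprintf("  span: %s -- %s\n", format(x$Datetime[1]),
                format(x$Datetime[n])))
  }
  miss <- vapply(series_channels(x), function(ch) mean(is.na(x[[ch]])),
                 numeric(1))
  if (length(miss)) {
    cat(sprintf("  channels: %s\n",
                paste(sprintf("%s (%.1f%% NA)", names(miss), 100 * miss),
                      collapse = ", ")))
  }
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Dominant sampling interval of a timestamp vector
#'
#' The epoch of a logger export is taken as the modal successive timestamp
#' difference; ties are broken toward the smaller interval, so occasional
#' long wear gaps never inflate the inferred epoch.
#'
#' @param timestamps `POSIXct` vector of at least 2 instants.
#' @return The dominant interval in seconds.
#' @examples
#' t <- as.POSIXct("2024-01-01", tz = "UTC") + c(0, 60, 120, 180, 300)
#' dominant_epoch(t)  # 60
#' @export
dominant_epoch <- function(timestamps) {
  if (length(timestamps) < 2) {
    abort("cannot infer epoch: need at least 2 timestamps")
  }
  d <- diff(as.numeric(timestamps))
  tab <- table(d)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)
}

#' Expand a series onto its complete epoch grid
#'
#' Wearable exports encode non-wear implicitly: rows are simply absent.
#' `regularize()` lays the series onto the full grid from its first to its
#' last timestamp at the given epoch; grid instants with no observation get
#' `NA` in every channel, and observed rows are untouched. Input timestamps
#' must sit on the grid within 1% of the epoch (clock jitter inside that
#' band is snapped to the grid; anything larger is an error rather than a
#' silent resample).
#'
#' @param x a `light_series`.
#' @param epoch grid interval in seconds; defaults to the series epoch.
#' @return A `light_series` on the complete grid.
#' @export
regularize <- function(x, epoch = series_epoch(x)) {
  if (is.na(epoch) || epoch <= 0) abort("epoch must be a positive number")
  n <- nrow(x)
  if (n <= 1) return(ls_rebuild(x, x, epoch = epoch))
  t <- x$Datetime
  offs <- as.numeric(t) - as.numeric(t[1])
  k <- round(offs / epoch)
  resid <- abs(offs - k * epoch)
  bad <- which(resid > 0.01 * epoch)
  if (length(bad)) {
    abort(sprintf("timestamp not aligned to %gs grid: %s",
                  epoch, format(t[bad[1]], usetz = TRUE)))
  }
  if (anyDuplicated(k)) abort("duplicate timestamps on the grid")
  m <- k[length(k)]
  idx <- match(0:m, k)
  grid <- t[1] + (0:m) * epoch
  out <- x[idx, , drop = FALSE]
  out$Datetime <- grid
  ls_rebuild(x, out, epoch = epoch)
}

#' Threshold specification shared by all threshold-family metrics
#'
#' @param mode one of `"above"` (value >= lower), `"below"` (value <=
#'   lower) or `"within"` (lower <= value <= upper, closed interval).
#' @param lower,upper bound(s) in the series' light units; `upper` is only
#'   used (and required) for `mode = "within"`.
#' @return A `threshold_spec` list.
#' @export
threshold_spec <- function(mode = c("above", "below", "within"),
                           lower, upper = NULL) {
  mode <- match.arg(mode)
  if (mode == "within") {
    if (is.null(upper)) abort("mode 'within' needs both bounds")
    if (lower > upper) abort("'within' requires lower <= upper")
  }
  structure(list(mode = mode, lower = lower, upper = upper),
            class = "threshold_spec")
}

# logical mask of epochs satisfying a threshold spec; NA stays NA
threshold_mask <- function(values, spec) {
  switch(spec$mode,
    above  = values >= spec$lower,
    below  = values <= spec$lower,
    within = values >= spec$lower & values <= spec$upper
  )
}

# coerce loose arguments into a threshold_spec: either a spec already, or
# mode + numeric bounds (length 2 for within)
as_threshold_spec <- function(threshold, mode = "above") {
  if (inherits(threshold, "threshold_spec")) return(threshold)
  if (mode == "within") {
    if (length(threshold) != 2) abort("'within' needs two bounds")
    threshold_spec("within", threshold[1], threshold[2])
  } else {
    threshold_spec(mode, threshold[1])
  }
}

#' Seconds since local midnight
#'
#' Time-of-day computations use local wall time in the series' timezone;
#' the value wraps modulo 86400.
#'
#' @param t `POSIXct` vector.
#' @return numeric seconds in `[0, 86400)`.
#' @export
time_of_day <- function(t) {
  as.numeric(t) - as.numeric(lubridate::floor_date(t, "day"))
}

# local calendar date in the series' own zone
local_date <- function(t) as.Date(t, tz = attr(t, "tzone") %||% "UTC")

# render seconds-since-midnight as HH:MM:SS (for messages and reports)
format_tod <- function(secs) {
  secs <- round(secs) %% 86400
  sprintf("%02d:%02d:%02d", secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60)
}

# fraction of grid epochs (first to last timestamp) with no usable value
missing_fraction <- function(x, channel = NULL) {
  n <- nrow(x)
  if (n == 0) return(1)
  v <- series_values(x, channel)
  ep <- series_epoch(x)
  if (is.na(ep) || n == 1) return(mean(is.na(v)))
  span <- as.numeric(x$Datetime[n]) - as.numeric(x$Datetime[1])
  m <- round(span / ep) + 1
  1 - sum(!is.na(v)) / m
}

# split a series at local-midnight boundaries; incomplete first/last days
# are kept and flagged via the "complete" attribute on each piece
split_days <- function(x) {
  if (nrow(x) == 0) return(list())
  dts <- local_date(x$Datetime)
  pieces <- split(seq_len(nrow(x)), dts)
  ep <- series_epoch(x)
  full_n <- if (is.na(ep)) NA_integer_ else round(86400 / ep)
  lapply(pieces, function(ix) {
    d <- ls_rebuild(x, x[ix, , drop = FALSE])
    attr(d, "complete") <- !is.na(full_n) && length(ix) == full_n
    d
  })
}
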