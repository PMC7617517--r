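#' Brightest or darkest period of the day
#'
#' Slides a window of duration `window` across the day and reports the
#' window with the highest (brightest) or lowest (darkest) mean level,
#' in the spirit of the M10/L5 statistics from rest--activity research.
#' Ties resolve to the earliest onset. With `loop = TRUE` the day is
#' treated circularly so the window may wrap across midnight.
#'
#' @inheritParams duration_above_threshold
#' @param period `"brightest"` or `"darkest"`.
#' @param window window duration in seconds; conventional defaults are
#'   10 h for the brightest and 5 h for the darkest period.
#' @param loop evaluate windows wrapping past the end of the series.
#' @return Four rows: `<period>_mean` (lx), `<period>_onset`,
#'   `<period>_midpoint`, `<period>_offset` (seconds since midnight;
#'   offset is the start of the window's last epoch).
#' @export
bright_dark_period <- function(x, period = c("brightest", "darkest"),
                               window = NULL, loop = FALSE,
                               channel = NULL, ignore_missing = TRUE) {
  period <- match.arg(period)
  window <- window %||% if (period == "brightest") 10 * 3600 else 5 * 3600
  prm <- list(period = period, window = window, loop = loop)
  g <- metric_guard(x, channel, ignore_missing, "bright_dark_period",
                    paste0(period, "_mean"), "lx", prm)
  mk_und <- function(reason, mf = NA_real_) {
    dplyr::bind_rows(lapply(
      paste0(period, "_", c("mean", "onset", "midpoint", "offset")),
      function(m) undefined_result("bright_dark_period", m,
                                   if (grepl("mean", m)) "lx"
                                   else "s since midnight", reason, prm, mf)))
  }
  if (g$stop) return(mk_und(g$result$Reason, g$result$MissingFraction))
  ep <- series_epoch(x)
  k <- round(window / ep)
  v <- g$values
  n <- length(v)
  if (!loop && k > n) return(mk_und("window longer than series"))
  if (loop) v <- c(v, v[seq_len(min(k - 1, n))])
  s <- cumsum(ifelse(is.na(v), 0, v))
  cnt <- cumsum(!is.na(v))
  nwin <- length(v) - k + 1
  i <- seq_len(nwin)
  tot <- s[i + k - 1] - c(0, s)[i]
  obs <- cnt[i + k - 1] - c(0, cnt)[i]
  means <- ifelse(obs > 0, tot / obs, NA_real_)
  if (all(is.na(means))) return(mk_und("no observed window"))
  best <- if (period == "brightest") which.max(means) else which.min(means)
  onset <- time_of_day(x$Datetime)[(best - 1) %% n + 1]
  mf <- g$missing_fraction
  row <- function(m, val, units) {
    metric_result("bright_dark_period", paste0(period, "_", m), val, units,
                  prm, mf)
  }
  dplyr::bind_rows(
    row("mean", means[best], "lx"),
    row("onset", onset, "s since midnight"),
    row("midpoint", (onset + window / 2) %% 86400, "s since midnight"),
    row("offset", (onset + window - ep) %% 86400, "s since midnight")
  )
}

#' Centroid of light exposure
#'
#' The exposure-weighted mean clock time of a day:
#' sum(tod_i * x_i) / sum(x_i). A day with zero total exposure has no
#' centroid and returns an undefined result.
#'
#' @inheritParams duration_above_threshold
#' @param circular use the circular (24 h clock-face) weighted mean.
#' @return One row; `Value` in seconds since local midnight.
#' @export
centroid_of_exposure <- function(x, channel = NULL, circular = FALSE,
                                 ignore_missing = TRUE) {
  g <- metric_guard(x, channel, ignore_missing, "centroid_of_exposure",
                    "centroid_of_exposure", "s since midnight")
  if (g$stop) return(g$result)
  v <- g$values
  tod <- time_of_day(x$Datetime)
  keep <- !is.na(v)
  v <- v[keep]; tod <- tod[keep]
  if (sum(v) == 0) {
    return(undefined_result("centroid_of_exposure", "centroid_of_exposure",
                            "s since midnight", "zero total exposure",
                            missing_fraction = g$missing_fraction))
  }
  val <- if (circular) {
    ang <- tod / 86400 * 2 * pi
    (atan2(sum(v * sin(ang)), sum(v * cos(ang))) / (2 * pi) * 86400) %% 86400
  } else {
    sum(tod * v) / sum(v)
  }
  metric_result("centroid_of_exposure", "centroid_of_exposure", val,
                "s since midnight", list(circular = circular),
                g$missing_fraction)
}

#' Midpoint of cumulative exposure
#'
#' The earliest epoch at which the running dose reaches half the day's
#' total.
#'
#' @inheritParams duration_above_threshold
#' @return One row; `Value` is the epoch-start time in seconds since
#'   local midnight.
#' @export
midpoint_cumulative_exposure <- function(x, channel = NULL,
                                         ignore_missing = TRUE) {
  g <- metric_guard(x, channel, ignore_missing,
                    "midpoint_cumulative_exposure",
                    "midpoint_cumulative_exposure", "s since midnight")
  if (g$stop) return(g$result)
  v <- ifelse(is.na(g$values), 0, g$values)
  tot <- sum(v)
  if (tot == 0) {
    return(undefined_result("midpoint_cumulative_exposure",
                            "midpoint_cumulative_exposure",
                            "s since midnight", "zero total exposure",
                            missing_fraction = g$missing_fraction))
  }
  i <- which(cumsum(v) >= tot / 2)[1]
  metric_result("midpoint_cumulative_exposure",
                "midpoint_cumulative_exposure",
                time_of_day(x$Datetime)[i], "s since midnight",
                missing_fraction = g$missing_fraction)
}

# bin a series to the rhythm grid and return values + clock-bin index
rhythm_bins <- function(x, bin_width, channel) {
  b <- aggregate_epochs(x, bin_width)
  v <- series_values(b, channel)
  h <- time_of_day(b$Datetime) %/% bin_width + 1
  list(values = v, bin = h, p = round(86400 / bin_width))
}

#' Interdaily stability (IS)
#'
#' How consistently the 24 h exposure profile repeats across days:
#' the variance of the mean 24 h profile relative to the total variance,
#' IS = (n * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2),
#' computed on the series binned to `bin_width` (p bins per 24 h cycle;
#' xbar_h is the across-days mean of clock bin h). IS is near 1 for a
#' perfectly repeating profile and near 0 for noise.
#'
#' @inheritParams duration_above_threshold
#' @param bin_width bin width in seconds; must divide 24 h (default 1 h).
#' @return One row; dimensionless. Undefined for constant input.
#' @export
interdaily_stability <- function(x, bin_width = 3600, channel = NULL,
                                 ignore_missing = TRUE) {
  if (86400 %% bin_width != 0) abort("bin_width must divide 24 h")
  g <- metric_guard(x, channel, ignore_missing, "interdaily_stability",
                    "interdaily_stability", "1",
                    list(bin_width = bin_width))
  if (g$stop) return(g$result)
  rb <- rhythm_bins(x, bin_width, channel)
  keep <- !is.na(rb$values)
  v <- rb$values[keep]; h <- rb$bin[keep]
  n <- length(v)
  xbar <- mean(v)
  den <- rb$p * sum((v - xbar)^2)
  if (den == 0 || n < 2) {
    return(undefined_result("interdaily_stability", "interdaily_stability",
                            "1", "zero variance",
                            list(bin_width = bin_width),
                            g$missing_fraction))
  }
  hourly <- tapply(v, h, mean)
  val <- n * sum((hourly - xbar)^2) / den
  metric_result("interdaily_stability", "interdaily_stability", val, "1",
                list(bin_width = bin_width), g$missing_fraction)
}

#' Intradaily variability (IV)
#'
#' Epoch-to-epoch fragmentation of the exposure rhythm on the binned
#' series: IV = (n * sum_i (x_i - x_{i-1})^2) / ((n - 1) * sum_i (x_i -
#' xbar)^2). Smooth rhythms give small IV; strict alternation gives
#' exactly 4 (for even length).
#'
#' @inheritParams interdaily_stability
#' @return One row; dimensionless. Undefined for constant input.
#' @export
intradaily_variability <- function(x, bin_width = 3600, channel = NULL,
                                   ignore_missing = TRUE) {
  if (86400 %% bin_width != 0) abort("bin_width must divide 24 h")
  g <- metric_guard(x, channel, ignore_missing, "intradaily_variability",
                    "intradaily_variability", "1",
                    list(bin_width = bin_width))
  if (g$stop) return(g$result)
  rb <- rhythm_bins(x, bin_width, channel)
  v <- rb$values[!is.na(rb$values)]
  n <- length(v)
  xbar <- mean(v)
  den <- (n - 1) * sum((v - xbar)^2)
  if (den == 0 || n < 2) {
    return(undefined_result("intradaily_variability",
                            "intradaily_variability", "1", "zero variance",
                            list(bin_width = bin_width),
                            g$missing_fraction))
  }
  val <- n * sum(diff(v)^2) / den
  metric_result("intradaily_variability", "intradaily_variability", val,
                "1", list(bin_width = bin_width), g$missing_fraction)
}

# recursive exponential smoother; missing inputs leave the state unchanged
# and produce a missing output
ema_filter <- function(v, lambda) {
  out <- rep(NA_real_, length(v))
  state <- NA_real_
  for (i in seq_along(v)) {
    if (is.na(v[i])) next
    state <- if (is.na(state)) v[i] else lambda * v[i] + (1 - lambda) * state
    out[i] <- state
  }
  out
}

#' Exponential moving average of a light channel
#'
#' First-order recursive smoother s_i = lambda * x_i + (1 - lambda) *
#' s_{i-1}, parameterised by its half-life: lambda = 1 - 2^(-epoch /
#' half_life), so the smoothed response to a step reaches 0.5 one
#' half-life after the step. Missing epochs leave the smoother state
#' unchanged and emit a missing output.
#'
#' @inheritParams duration_above_threshold
#' @param half_life smoothing half-life in seconds (default 2 h).
#' @return The series with an added `<channel>_ema` channel.
#' @export
exponential_moving_average <- function(x, half_life = 2 * 3600,
                                       channel = NULL) {
  channel <- channel %||% series_channels(x)[1]
  ep <- series_epoch(x)
  lambda <- 1 - 2^(-ep / half_life)
  out <- x
  nm <- paste0(channel, "_ema")
  out[[nm]] <- ema_filter(x[[channel]], lambda)
  ls_rebuild(x, out, channels = c(series_channels(x), nm))
}

#' Disparity index
#'
#' Mean absolute log-ratio of successive levels, DI = mean over i of
#' |ln(x_{i+1} + 1) - ln(x_i + 1)|: zero for a constant day, large for
#' erratic exposure. The +1 keeps true darkness finite.
#'
#' @inheritParams duration_above_threshold
#' @return One row; dimensionless.
#' @export
disparity_index <- function(x, channel = NULL, ignore_missing = TRUE) {
  g <- metric_guard(x, channel, ignore_missing, "disparity_index",
                    "disparity_index", "1")
  if (g$stop) return(g$result)
  v <- g$values[!is.na(g$values)]
  if (length(v) < 2) {
    return(undefined_result("disparity_index", "disparity_index", "1",
                            "fewer than 2 observations",
                            missing_fraction = g$missing_fraction))
  }
  val <- mean(abs(diff(log(v + 1))))
  metric_result("disparity_index", "disparity_index", val, "1",
                missing_fraction = g$missing_fraction)
}

#' Cumulative light dose
#'
#' Time-integrated exposure sum(x_i * epoch), in lux-hours.
#'
#' @inheritParams duration_above_threshold
#' @return One row; `Value` in lx*h.
#' @export
dose <- function(x, channel = NULL, ignore_missing = TRUE) {
  g <- metric_guard(x, channel, ignore_missing, "dose", "dose", "lx*h")
  if (g$stop) return(g$result)
  val <- sum(g$values, na.rm = TRUE) * series_epoch(x) / 3600
  metric_result("dose", "dose", val, "lx*h",
                missing_fraction = g$missing_fraction)
}

#' Barroso lighting metrics
#'
#' Percentile-based day structure statistics. Per local day: the bright
#' (dark) threshold is the day's upper (lower) `bright_quantile`
#' (`dark_quantile`) percentile; bright/dark mean levels average the
#' values at or beyond those thresholds; bright/dark clusters are the
#' longest runs at or beyond them. The first six statistics are averaged
#' across days; circadian variation is the coefficient of variation of
#' the daily mean levels.
#'
#' @inheritParams duration_above_threshold
#' @param bright_quantile,dark_quantile percentiles defining bright and
#'   dark (defaults 0.9 and 0.1).
#' @return Seven metric-result rows.
#' @export
barroso_metrics <- function(x, bright_quantile = 0.9, dark_quantile = 0.1,
                            channel = NULL, ignore_missing = TRUE) {
  prm <- list(bright_quantile = bright_quantile,
              dark_quantile = dark_quantile)
  g <- metric_guard(x, channel, ignore_missing, "barroso",
                    "bright_threshold", "lx", prm)
  nms <- c("bright_threshold", "dark_threshold", "bright_mean_level",
           "dark_mean_level", "bright_cluster", "dark_cluster",
           "circadian_variation")
  unit_of <- function(m) {
    if (grepl("cluster", m)) "s" else if (m == "circadian_variation") "1"
    else "lx"
  }
  if (g$stop) {
    return(dplyr::bind_rows(lapply(nms, function(m) {
      undefined_result("barroso", m, unit_of(m), g$result$Reason, prm,
                       g$result$MissingFraction)
    })))
  }
  ep <- series_epoch(x)
  longest_run <- function(mask) {
    mask[is.na(mask)] <- FALSE
    r <- rle(mask)
    if (!any(r$values)) 0 else max(r$lengths[r$values]) * ep
  }
  per_day <- lapply(split_days(x), function(d) {
    v <- series_values(d, channel)
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    bt <- as.numeric(quantile(v, bright_quantile))
    dk <- as.numeric(quantile(v, dark_quantile))
    vv <- series_values(d, channel)
    c(bright_threshold = bt, dark_threshold = dk,
      bright_mean_level = mean(v[v >= bt]),
      dark_mean_level = mean(v[v <= dk]),
      bright_cluster = longest_run(vv >= bt),
      dark_cluster = longest_run(vv <= dk),
      daily_mean = mean(v))
  })
  per_day <- do.call(rbind, per_day[!vapply(per_day, is.null, logical(1))])
  means <- colMeans(per_day)
  mf <- g$missing_fraction
  rows <- lapply(nms[1:6], function(m) {
    metric_result("barroso", m, means[[m]], unit_of(m), prm, mf)
  })
  dm <- per_day[, "daily_mean"]
  cv_row <- if (length(dm) < 2) {
    undefined_result("barroso", "circadian_variation", "1",
                     "fewer than 2 days", prm, mf)
  } else if (mean(dm) == 0) {
    undefined_result("barroso", "circadian_variation", "1",
                     "zero mean level", prm, mf)
  } else {
    metric_result("barroso", "circadian_variation", sd(dm) / mean(dm),
                  "1", prm, mf)
  }
  dplyr::bind_rows(c(rows, list(cv_row)))
}
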