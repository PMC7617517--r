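#' Time spent above, below or within a light-level band
#'
#' Counts qualifying epochs and multiplies by the epoch length, so the
#' result is always an exact multiple of the sampling interval.
#' Comparators are inclusive: above means `>=`, below means `<=`, within
#' is the closed interval.
#'
#' @param x a `light_series` (typically one local day).
#' @param threshold a [threshold_spec()], or numeric bound(s) combined
#'   with `mode`.
#' @param mode used when `threshold` is numeric.
#' @param channel light channel; defaults to the first.
#' @param ignore_missing drop missing epochs (default) instead of
#'   declaring the result undefined.
#' @return One metric-result row; `Value` is a duration in seconds.
#' @examples
#' t0 <- as.POSIXct("2024-03-01", tz = "UTC")
#' s <- light_series(t0 + 60 * (0:5), c(0, 300, 300, 0, 300, 0))
#' duration_above_threshold(s, 250)$Value  # 180
#' @export
duration_above_threshold <- function(x, threshold, mode = "above",
                                     channel = NULL, ignore_missing = TRUE) {
  spec <- as_threshold_spec(threshold, mode)
  nm <- paste0("duration_", spec$mode)
  g <- metric_guard(x, channel, ignore_missing, "duration_above_threshold",
                    nm, "s", spec)
  if (g$stop) return(g$result)
  mask <- threshold_mask(g$values, spec)
  metric_result("duration_above_threshold", nm,
                sum(mask, na.rm = TRUE) * series_epoch(x), "s",
                spec, g$missing_fraction)
}

#' Mean clock time of epochs satisfying a threshold
#'
#' The mean light timing (MLiT-style) statistic: the average local
#' time-of-day of all epoch starts whose level satisfies the comparator.
#' Set `circular = TRUE` for the circular mean when qualifying times may
#' straddle midnight.
#'
#' @inheritParams duration_above_threshold
#' @param circular use the circular mean on the 24 h clock face.
#' @return One row; `Value` in seconds since local midnight, or undefined
#'   when no epoch qualifies.
#' @export
timing_above_threshold <- function(x, threshold, mode = "above",
                                   channel = NULL, circular = FALSE,
                                   ignore_missing = TRUE) {
  spec <- as_threshold_spec(threshold, mode)
  nm <- paste0("timing_", spec$mode)
  g <- metric_guard(x, channel, ignore_missing, "timing_above_threshold",
                    nm, "s since midnight", spec)
  if (g$stop) return(g$result)
  mask <- threshold_mask(g$values, spec)
  tod <- time_of_day(x$Datetime)[which(mask)]
  if (!length(tod)) {
    return(undefined_result("timing_above_threshold", nm, "s since midnight",
                            "no epochs satisfy the threshold", spec,
                            g$missing_fraction))
  }
  metric_result("timing_above_threshold", nm, mean_tod(tod, circular),
                "s since midnight", spec, g$missing_fraction)
}

#' Longest continuous period satisfying a threshold
#'
#' The longest run of qualifying epochs; non-qualifying interruptions no
#' longer than `max_interrupt` do not break a run (and count toward its
#' duration, since the run spans them).
#'
#' @inheritParams duration_above_threshold
#' @param max_interrupt longest tolerated interruption, in seconds.
#' @return One row; `Value` is the longest run duration in seconds.
#' @export
period_above_threshold <- function(x, threshold, mode = "above",
                                   max_interrupt = 0, channel = NULL,
                                   ignore_missing = TRUE) {
  spec <- as_threshold_spec(threshold, mode)
  nm <- paste0("period_", spec$mode)
  g <- metric_guard(x, channel, ignore_missing, "period_above_threshold",
                    nm, "s", spec)
  if (g$stop) return(g$result)
  mask <- threshold_mask(g$values, spec)
  spans <- merge_runs(mask, series_epoch(x), max_interrupt)
  val <- if (nrow(spans) == 0) 0
         else max(spans$end - spans$start + 1) * series_epoch(x)
  metric_result("period_above_threshold", nm, val, "s",
                c(spec, list(max_interrupt = max_interrupt)),
                g$missing_fraction)
}

#' Number of threshold crossings
#'
#' Counts sign changes of the comparator outcome between successive
#' non-missing epochs (comparisons bridge missing epochs).
#'
#' @inheritParams duration_above_threshold
#' @return One row; `Value` is the crossing count.
#' @export
frequency_crossing_threshold <- function(x, threshold, mode = "above",
                                         channel = NULL,
                                         ignore_missing = TRUE) {
  spec <- as_threshold_spec(threshold, mode)
  g <- metric_guard(x, channel, ignore_missing, "frequency_crossing_threshold",
                    "frequency_crossing", "1", spec)
  if (g$stop) return(g$result)
  mask <- threshold_mask(g$values, spec)
  mask <- mask[!is.na(mask)]
  val <- if (length(mask) < 2) 0 else sum(diff(mask) != 0)
  metric_result("frequency_crossing_threshold", "frequency_crossing",
                val, "1", spec, g$missing_fraction)
}

#' Light level sustained for a given total duration
#'
#' For `mode = "above"`: the highest threshold T such that the time spent
#' at or above T is at least `duration` -- i.e. the k-th largest value
#' with k = round(duration / epoch). `mode = "below"` is the mirror image
#' (k-th smallest).
#'
#' @inheritParams duration_above_threshold
#' @param duration target duration in seconds; must not exceed the
#'   series' observed span.
#' @return One row; `Value` in the series' light units.
#' @export
threshold_for_duration <- function(x, duration, mode = c("above", "below"),
                                   channel = NULL, ignore_missing = TRUE) {
  mode <- match.arg(mode)
  nm <- paste0("threshold_", mode, "_for_duration")
  g <- metric_guard(x, channel, ignore_missing, "threshold_for_duration",
                    nm, "lx", list(duration = duration))
  if (g$stop) return(g$result)
  v <- g$values[!is.na(g$values)]
  ep <- series_epoch(x)
  k <- round(duration / ep)
  if (k < 1 || k > length(v)) {
    abort(sprintf("duration %gs exceeds the series' observed %gs",
                  duration, length(v) * ep))
  }
  sorted <- sort(v, decreasing = (mode == "above"))
  metric_result("threshold_for_duration", nm, sorted[k], "lx",
                list(duration = duration, mode = mode), g$missing_fraction)
}

# maximal spans of TRUE runs, merging runs separated by interior FALSE/NA
# runs of at most max_interrupt seconds; returns start/end indices
merge_runs <- function(mask, epoch, max_interrupt = 0) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ti <- which(r$values)
  if (!length(ti)) return(tibble::tibble(start = integer(), end = integer()))
  out_start <- starts[ti[1]]
  out_end <- ends[ti[1]]
  res <- list()
  for (j in ti[-1]) {
    gap <- (starts[j] - out_end[length(out_end)] - 1) * epoch
    if (gap <= max_interrupt) {
      out_end[length(out_end)] <- ends[j]
    } else {
      out_start <- c(out_start, starts[j])
      out_end <- c(out_end, ends[j])
    }
  }
  tibble::tibble(start = out_start, end = out_end)
}

#' Pulses of light satisfying a threshold
#'
#' Detects bouts ("pulses") of qualifying light: runs of epochs satisfying
#' the comparator, merged across interruptions no longer than
#' `max_interrupt`, then filtered to a minimum duration. Seven statistics
#' describe the pulses of a day: their count, the mean level inside
#' pulses, mean and total pulse duration, and the mean onset, midpoint
#' and offset clock times. Onset is the start of the first epoch of a
#' pulse; offset is the start of its last epoch (one epoch before the
#' pulse ends); midpoint is onset + duration / 2.
#'
#' @inheritParams duration_above_threshold
#' @param min_duration minimum pulse duration in seconds (default 8 min).
#' @param max_interrupt longest interruption merged into a pulse, in
#'   seconds (default 2 min). Interruptions count toward pulse duration.
#' @return Seven metric-result rows. With zero pulses the count is 0 and
#'   the remaining six are undefined.
#' @export
pulses_above_threshold <- function(x, threshold, mode = "above",
                                   min_duration = 8 * 60,
                                   max_interrupt = 2 * 60,
                                   channel = NULL, ignore_missing = TRUE) {
  spec <- as_threshold_spec(threshold, mode)
  ep <- series_epoch(x)
  if (min_duration < ep) abort("min_duration must be at least one epoch")
  prm <- c(spec, list(min_duration = min_duration,
                      max_interrupt = max_interrupt))
  pre <- paste0("pulses_", spec$mode, "_")
  g <- metric_guard(x, channel, ignore_missing, "pulses_above_threshold",
                    paste0(pre, "count"), "1", prm)
  if (g$stop && is.na(g$result$Value)) {
    # all-missing day: every pulse statistic is undefined
    res <- lapply(c("count", "mean_level", "mean_duration", "total_duration",
                    "mean_onset", "mean_midpoint", "mean_offset"),
                  function(m) undefined_result("pulses_above_threshold",
                                               paste0(pre, m), "1",
                                               g$result$Reason, prm))
    return(dplyr::bind_rows(res))
  }
  mask <- threshold_mask(g$values, spec)
  spans <- merge_runs(mask, ep, max_interrupt)
  spans <- spans[(spans$end - spans$start + 1) * ep >= min_duration, ,
                 drop = FALSE]
  mf <- g$missing_fraction
  row <- function(metric, value, units) {
    metric_result("pulses_above_threshold", paste0(pre, metric),
                  value, units, prm, mf)
  }
  und <- function(metric, units) {
    undefined_result("pulses_above_threshold", paste0(pre, metric),
                     units, "no pulses detected", prm, mf)
  }
  npulse <- nrow(spans)
  if (npulse == 0) {
    return(dplyr::bind_rows(
      row("count", 0, "1"),
      und("mean_level", "lx"), und("mean_duration", "s"),
      und("total_duration", "s"), und("mean_onset", "s since midnight"),
      und("mean_midpoint", "s since midnight"),
      und("mean_offset", "s since midnight")
    ))
  }
  durs <- (spans$end - spans$start + 1) * ep
  tod <- time_of_day(x$Datetime)
  levels <- mapply(function(a, b) mean(g$values[a:b], na.rm = TRUE),
                   spans$start, spans$end)
  onset <- tod[spans$start]
  offset <- tod[spans$end]
  midpoint <- (onset + durs / 2) %% 86400
  dplyr::bind_rows(
    row("count", npulse, "1"),
    row("mean_level", mean(levels), "lx"),
    row("mean_duration", mean(durs), "s"),
    row("total_duration", sum(durs), "s"),
    row("mean_onset", mean_tod(onset), "s since midnight"),
    row("mean_midpoint", mean_tod(midpoint), "s since midnight"),
    row("mean_offset", mean_tod(offset), "s since midnight")
  )
}
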