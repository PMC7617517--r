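# One metric result row. Undefined outcomes (zero variance, no qualifying
# epochs, ...) carry value NA plus a Reason -- never a silent zero.
metric_result <- function(family, metric, value, units,
                          params = list(), missing_fraction = NA_real_,
                          reason = NA_character_) {
  tibble::tibble(
    Family = family, Metric = metric,
    Value = as.numeric(value), Units = units,
    Params = list(params),
    MissingFraction = missing_fraction,
    Reason = reason
  )
}

undefined_result <- function(family, metric, units, reason,
                             params = list(), missing_fraction = NA_real_) {
  metric_result(family, metric, NA_real_, units, params,
                missing_fraction, reason)
}

# shared entry guard: empty input / all-missing input / ignore_missing=FALSE
# with any missing value short-circuits to an undefined result (returns NULL
# when the metric may proceed, with the cleaned value vector in the parent).
metric_guard <- function(x, channel, ignore_missing, family, metric, units,
                         params = list()) {
  if (nrow(x) == 0) abort(sprintf("%s: empty series", metric))
  v <- series_values(x, channel)
  mf <- missing_fraction(x, channel)
  if (all(is.na(v))) {
    return(list(stop = TRUE,
                result = undefined_result(family, metric, units,
                                          "all values missing", params, mf)))
  }
  if (!ignore_missing && (anyNA(v) || mf > 0)) {
    return(list(stop = TRUE,
                result = undefined_result(family, metric, units,
                                          "missing values present", params, mf)))
  }
  list(stop = FALSE, values = v, missing_fraction = mf)
}

# arithmetic or circular mean of seconds-since-midnight
mean_tod <- function(tod, circular = FALSE) {
  if (!circular) return(mean(tod))
  ang <- tod / 86400 * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  (m / (2 * pi) * 86400) %% 86400
}

#' Registry of all implemented exposure metrics
#'
#' Enumerates every metric exactly once: 61 metrics across 17 families,
#' from threshold durations and pulse statistics to circadian rhythm
#' indices and modelled non-visual responses. The registry backs
#' [compute_metrics()] and the command line.
#'
#' @return A tibble with one row per metric: `Family`, `Metric`, `Units`,
#'   `Kind` (`scalar`, `duration`, `timing`, `count` or `series`), `Scope`
#'   (`day` for per-day metrics, `id` for whole-recording metrics) and a
#'   list-column `Fn` of compute closures `function(series, params)`.
#' @examples
#' reg <- metric_registry()
#' length(unique(reg$Family))  # 17
#' nrow(reg)                   # 61
#' @export
metric_registry <- function() {
  rows <- list()
  add <- function(family, metric, units, kind, scope, fn) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      Family = family, Metric = metric, Units = units,
      Kind = kind, Scope = scope, Fn = list(fn)
    )
  }
  thr <- function(p, mode) {
    if (mode == "within") as_threshold_spec(p$threshold_within, "within")
    else as_threshold_spec(p$threshold, mode)
  }

  for (mode in c("above", "below", "within")) {
    local({
      m <- mode
      add("duration_above_threshold", paste0("duration_", m), "s",
          "duration", "day",
          function(x, p) duration_above_threshold(x, thr(p, m),
                                                  ignore_missing = p$ignore_missing))
      add("timing_above_threshold", paste0("timing_", m), "s since midnight",
          "timing", "day",
          function(x, p) timing_above_threshold(x, thr(p, m),
                                                ignore_missing = p$ignore_missing))
      add("period_above_threshold", paste0("period_", m), "s",
          "duration", "day",
          function(x, p) period_above_threshold(x, thr(p, m),
                                                max_interrupt = p$max_interrupt,
                                                ignore_missing = p$ignore_missing))
      for (pm in c("count", "mean_level", "mean_duration", "total_duration",
                   "mean_onset", "mean_midpoint", "mean_offset")) {
        local({
          pmm <- pm
          units <- switch(pmm, count = "1", mean_level = "lx",
                          mean_duration = , total_duration = "s",
                          "s since midnight")
          kind <- switch(pmm, count = "count",
                         mean_level = "scalar",
                         mean_duration = , total_duration = "duration",
                         "timing")
          add("pulses_above_threshold", paste0("pulses_", m, "_", pmm),
              units, kind, "day",
              function(x, p) {
                res <- pulses_above_threshold(
                  x, thr(p, m), min_duration = p$pulse_min_duration,
                  max_interrupt = p$pulse_max_interrupt,
                  ignore_missing = p$ignore_missing)
                res[res$Metric == paste0("pulses_", m, "_", pmm), ]
              })
        })
      }
    })
  }
  for (mode in c("above", "below")) {
    local({
      m <- mode
      add("threshold_for_duration", paste0("threshold_", m, "_for_duration"),
          "lx", "scalar", "day",
          function(x, p) threshold_for_duration(x, p$duration, mode = m,
                                                ignore_missing = p$ignore_missing))
    })
  }
  add("frequency_crossing_threshold", "frequency_crossing", "1", "count", "day",
      function(x, p) frequency_crossing_threshold(x, thr(p, "above"),
                                                  ignore_missing = p$ignore_missing))
  for (per in c("brightest", "darkest")) {
    local({
      pr <- per
      for (pm in c("mean", "onset", "midpoint", "offset")) {
        local({
          pmm <- pm
          units <- if (pmm == "mean") "lx" else "s since midnight"
          add("bright_dark_period", paste0(pr, "_", pmm), units,
              if (pmm == "mean") "scalar" else "timing", "day",
              function(x, p) {
                res <- bright_dark_period(
                  x, period = pr,
                  window = if (pr == "brightest") p$bright_window else p$dark_window,
                  loop = p$loop, ignore_missing = p$ignore_missing)
                res[res$Metric == paste0(pr, "_", pmm), ]
              })
        })
      }
    })
  }
  add("centroid_of_exposure", "centroid_of_exposure", "s since midnight",
      "timing", "day",
      function(x, p) centroid_of_exposure(x, ignore_missing = p$ignore_missing))
  add("midpoint_cumulative_exposure", "midpoint_cumulative_exposure",
      "s since midnight", "timing", "day",
      function(x, p) midpoint_cumulative_exposure(x,
                                                  ignore_missing = p$ignore_missing))
  add("interdaily_stability", "interdaily_stability", "1", "scalar", "id",
      function(x, p) interdaily_stability(x, bin_width = p$bin_width,
                                          ignore_missing = p$ignore_missing))
  add("intradaily_variability", "intradaily_variability", "1", "scalar", "id",
      function(x, p) intradaily_variability(x, bin_width = p$bin_width,
                                            ignore_missing = p$ignore_missing))
  add("exponential_moving_average", "exponential_moving_average", "lx",
      "series", "id",
      function(x, p) exponential_moving_average(x, half_life = p$half_life))
  add("disparity_index", "disparity_index", "1", "scalar", "day",
      function(x, p) disparity_index(x, ignore_missing = p$ignore_missing))
  add("dose", "dose", "lx*h", "scalar", "day",
      function(x, p) dose(x, ignore_missing = p$ignore_missing))
  for (bm in c("bright_threshold", "dark_threshold", "bright_mean_level",
               "dark_mean_level", "bright_cluster", "dark_cluster",
               "circadian_variation")) {
    local({
      b <- bm
      units <- switch(b, bright_cluster = , dark_cluster = "s",
                      circadian_variation = "1", "lx")
      add("barroso", b, units,
          if (grepl("cluster", b)) "duration" else "scalar", "id",
          function(x, p) {
            res <- barroso_metrics(x, bright_quantile = p$bright_quantile,
                                   dark_quantile = p$dark_quantile,
                                   ignore_missing = p$ignore_missing)
            res[res$Metric == b, ]
          })
    })
  }
  add("nvRD", "nvrd", "1", "series", "day",
      function(x, p) nvrd(x, params = p$response_params))
  add("nvRD", "nvrd_cumulative_response", "response*h", "scalar", "day",
      function(x, p) nvrd_cumulative_response(x, params = p$response_params,
                                              ignore_missing = p$ignore_missing))
  add("nvRC", "nvrc", "1", "series", "day",
      function(x, p) nvrc(x, params = p$response_params))
  for (cm in c("circadian_disturbance", "circadian_bias",
               "relative_amplitude_error")) {
    local({
      cc <- cm
      add("nvRC", cc, "1", "scalar", "day",
          function(x, p) {
            if (is.null(p$reference_series)) {
              return(undefined_result("nvRC", cc, "1",
                                      "no reference response supplied"))
            }
            res <- nvrc_compare(nvrc(x, params = p$response_params),
                                p$reference_series)
            res[res$Metric == cc, ]
          })
    })
  }
  dplyr::bind_rows(rows)
}

#' Default parameters for the metric driver
#'
#' @param ... overrides for individual entries.
#' @return Named list of parameters consumed by [compute_metrics()]:
#'   threshold (250 lx, the conventional "bright light" cut), a closed
#'   `threshold_within` band, pulse spec (minimum duration 8 min, maximum
#'   interruption 2 min), brightest/darkest window lengths (10 h / 5 h),
#'   rhythm bin width (1 h), smoothing half-life (2 h), duration for
#'   threshold-for-duration (1 h), Barroso percentiles (0.9 / 0.1), and
#'   the non-visual response parameters from [response_params()].
#' @export
default_metric_params <- function(...) {
  p <- list(
    threshold = 250,
    threshold_within = c(10, 1000),
    duration = 3600,
    max_interrupt = 0,
    pulse_min_duration = 8 * 60,
    pulse_max_interrupt = 2 * 60,
    bright_window = 10 * 3600,
    dark_window = 5 * 3600,
    loop = FALSE,
    bin_width = 3600,
    half_life = 2 * 3600,
    bright_quantile = 0.9,
    dark_quantile = 0.1,
    response_params = response_params(),
    reference_series = NULL,
    ignore_missing = TRUE
  )
  utils::modifyList(p, list(...))
}

#' Compute a set of metrics over ids and days
#'
#' The driver maps registry metrics over one series or a list of series:
#' day-scope metrics are evaluated once per local day (days split at local
#' midnight; incomplete edge days are included and flagged), id-scope
#' metrics once per recording. Series-valued entries (smoothed or response
#' series) are skipped here; call their functions directly.
#'
#' @param series a `light_series` or a (possibly named) list of them.
#' @param metrics character vector of registry metric names; `NULL` means
#'   every non-series metric.
#' @param params list from [default_metric_params()].
#' @return Long tibble: `Id`, `Day`, `Family`, `Metric`, `Value`, `Units`,
#'   `MissingFraction`, `Reason`, `CompleteDay`.
#' @export
compute_metrics <- function(series, metrics = NULL,
                            params = default_metric_params()) {
  if (inherits(series, "light_series")) series <- list(series)
  reg <- metric_registry()
  reg <- reg[reg$Kind != "series", , drop = FALSE]
  if (!is.null(metrics)) {
    unknown <- setdiff(metrics, reg$Metric)
    if (length(unknown)) {
      abort(paste0("unknown metrics: ", paste(unknown, collapse = ", ")))
    }
    reg <- reg[reg$Metric %in% metrics, , drop = FALSE]
  }
  out <- list()
  for (s in series) {
    days <- split_days(s)
    for (i in seq_len(nrow(reg))) {
      fn <- reg$Fn[[i]]
      if (reg$Scope[i] == "id") {
        res <- fn(s, params)
        res$Id <- series_id(s)
        res$Day <- as.Date(NA)
        res$CompleteDay <- NA
        out[[length(out) + 1]] <- res
      } else {
        for (d in days) {
          res <- fn(d, params)
          res$Id <- series_id(s)
          res$Day <- local_date(d$Datetime[1])
          res$CompleteDay <- isTRUE(attr(d, "complete"))
          out[[length(out) + 1]] <- res
        }
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$Params <- NULL
  dplyr::relocate(res, "Id", "Day", "Family", "Metric", "Value", "Units",
                  "MissingFraction", "Reason", "CompleteDay")
}

#' Write metric results to long-format CSV or JSON
#'
#' @param results tibble from [compute_metrics()].
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(results, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(results, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    readr::write_csv(results, path, na = "")
  }
  invisible(path)
}
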