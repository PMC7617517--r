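#' Parameters of the non-visual light-response model
#'
#' The modelled non-visual responses combine three ingredients: an
#' exponential history filter (light adaptation with half-life
#' `history_half_life`), a Hill dose--response on the filtered melanopic
#' level (exponent `hill_exponent`, half-maximum `half_max`), and -- for
#' the circadian response -- a sinusoidal sensitivity gate over the 24 h
#' day (relative amplitude `amplitude`, peak phase `peak_phase`).
#' All defaults are configuration, not constants.
#'
#' @param hill_exponent Hill exponent n > 0 (default 2).
#' @param half_max half-maximum level C50 in melanopic EDI lux
#'   (default 100).
#' @param history_half_life history-filter half-life in seconds
#'   (default 60 min).
#' @param amplitude circadian sensitivity amplitude a in `[0, 1]`
#'   (default 0.5).
#' @param peak_phase clock time of peak sensitivity, seconds since local
#'   midnight (default 03:00).
#' @return A `response_params` list.
#' @export
response_params <- function(hill_exponent = 2, half_max = 100,
                            history_half_life = 60 * 60,
                            amplitude = 0.5, peak_phase = 3 * 3600) {
  if (hill_exponent <= 0 || half_max <= 0) {
    abort("hill_exponent and half_max must be positive")
  }
  if (amplitude < 0 || amplitude > 1) abort("amplitude must be in [0, 1]")
  structure(list(hill_exponent = hill_exponent, half_max = half_max,
                 history_half_life = history_half_life,
                 amplitude = amplitude, peak_phase = peak_phase %% 86400),
            class = "response_params")
}

#' Non-visual direct response (nvRD)
#'
#' Models the immediate non-visual drive of melanopic light: the input is
#' first passed through an exponential history filter (same recursion as
#' [exponential_moving_average()], half-life `history_half_life`) to give
#' an effective level E(t), then through a Hill function R_D = E^n /
#' (E^n + C50^n), bounded in `[0, 1]`.
#'
#' @param x a `light_series` whose channel is melanopic EDI in lux.
#' @param params a [response_params()] list.
#' @param channel light channel; defaults to the first.
#' @return The series with added channels `effective_light` and `nvrd`.
#' @export
nvrd <- function(x, params = response_params(), channel = NULL) {
  channel <- channel %||% series_channels(x)[1]
  ep <- series_epoch(x)
  lambda <- 1 - 2^(-ep / params$history_half_life)
  e <- ema_filter(x[[channel]], lambda)
  n <- params$hill_exponent
  r <- e^n / (e^n + params$half_max^n)
  out <- x
  out$effective_light <- e
  out$nvrd <- r
  ls_rebuild(x, out,
             channels = c(series_channels(x), "effective_light", "nvrd"))
}

#' Cumulative non-visual direct response
#'
#' Integrates the direct response over time: sum(R_D * epoch), in
#' response-hours (1 means one hour at full drive).
#'
#' @inheritParams nvrd
#' @param ignore_missing drop missing epochs (default) instead of
#'   declaring the result undefined.
#' @return One metric-result row; `Value` in response-hours.
#' @export
nvrd_cumulative_response <- function(x, params = response_params(),
                                     channel = NULL, ignore_missing = TRUE) {
  g <- metric_guard(x, channel, ignore_missing, "nvRD",
                    "nvrd_cumulative_response", "response*h", params)
  if (g$stop) return(g$result)
  r <- series_values(nvrd(x, params, channel), "nvrd")
  val <- sum(r, na.rm = TRUE) * series_epoch(x) / 3600
  metric_result("nvRD", "nvrd_cumulative_response", val, "response*h",
                params, g$missing_fraction)
}

#' Non-visual circadian response (nvRC)
#'
#' The direct response modulated by a sinusoidal circadian sensitivity
#' gate: C(t) = R_D(t) * (1 + a * cos(2 * pi * (tod(t) - phi) / 24 h)) /
#' (1 + a), clipped to `[0, 1]`; sensitivity peaks at clock time `phi`.
#'
#' @inheritParams nvrd
#' @return The series with an added `nvrc` channel (plus the `nvrd`
#'   intermediates).
#' @export
nvrc <- function(x, params = response_params(), channel = NULL) {
  out <- nvrd(x, params, channel)
  tod <- time_of_day(out$Datetime)
  gate <- (1 + params$amplitude *
             cos(2 * pi * (tod - params$peak_phase) / 86400)) /
          (1 + params$amplitude)
  out$nvrc <- pmin(pmax(out$nvrd * gate, 0), 1)
  ls_rebuild(out, out, channels = c(series_channels(out), "nvrc"))
}

#' Compare a circadian response against a reference
#'
#' Quantifies how a realised circadian response C(t) departs from a
#' reference C_ref(t) (e.g. the response to available daylight) on the
#' same grid: circadian disturbance CD = time-average of |C - C_ref|;
#' circadian bias CB = time-average of (C - C_ref) (signed: positive
#' means over-stimulation); relative amplitude error RAE =
#' |amp(C) - amp(C_ref)| / amp(C_ref) with amp = max - min over the day.
#'
#' @param x a `light_series` with an `nvrc` channel (from [nvrc()]).
#' @param reference a `light_series` on the identical grid with its own
#'   `nvrc` (or single) response channel.
#' @param channel,reference_channel response channel names; default
#'   `"nvrc"` falling back to the first channel.
#' @return Three metric-result rows: `circadian_disturbance`,
#'   `circadian_bias`, `relative_amplitude_error`. RAE is undefined when
#'   the reference has zero amplitude.
#' @export
nvrc_compare <- function(x, reference, channel = NULL,
                         reference_channel = NULL) {
  pick <- function(s, ch) {
    ch <- ch %||% if ("nvrc" %in% names(s)) "nvrc" else series_channels(s)[1]
    series_values(s, ch)
  }
  if (nrow(x) != nrow(reference) ||
      !isTRUE(all.equal(as.numeric(x$Datetime),
                        as.numeric(reference$Datetime)))) {
    abort("response and reference are not on the same time grid")
  }
  cc <- pick(x, channel)
  cr <- pick(reference, reference_channel)
  keep <- !is.na(cc) & !is.na(cr)
  mf <- 1 - mean(keep)
  if (!any(keep)) {
    return(dplyr::bind_rows(lapply(
      c("circadian_disturbance", "circadian_bias",
        "relative_amplitude_error"),
      function(m) undefined_result("nvRC", m, "1", "no overlapping values",
                                   missing_fraction = mf))))
  }
  d <- cc[keep] - cr[keep]
  amp <- function(v) max(v) - min(v)
  rae <- if (amp(cr[keep]) == 0) {
    undefined_result("nvRC", "relative_amplitude_error", "1",
                     "reference has zero amplitude", missing_fraction = mf)
  } else {
    metric_result("nvRC", "relative_amplitude_error",
                  abs(amp(cc[keep]) - amp(cr[keep])) / amp(cr[keep]), "1",
                  missing_fraction = mf)
  }
  dplyr::bind_rows(
    metric_result("nvRC", "circadian_disturbance", mean(abs(d)), "1",
                  missing_fraction = mf),
    metric_result("nvRC", "circadian_bias", mean(d), "1",
                  missing_fraction = mf),
    rae
  )
}
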