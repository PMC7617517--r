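#' Describe a synthetic light-exposure scenario
#'
#' A scenario emulates a small field study with wearable light loggers:
#' multi-day per-participant series at a fixed epoch, a diurnal
#' piecewise-constant (or sinusoidal) template spanning night to daylight
#' levels, multiplicative log-normal noise, wear gaps (rows removed, so
#' missingness is implicit) and a jittered sleep diary. Everything is
#' deterministic under `seed`, and the generator records its own ground
#' truth (gap positions, template daily dose, daylight pulse blocks) so
#' downstream code can be tested against construction rather than
#' re-computation.
#'
#' @param n_ids participants.
#' @param days days per participant.
#' @param epoch sampling interval, seconds.
#' @param start first local midnight of the recording.
#' @param tz IANA timezone.
#' @param photoperiod numeric `c(start, end)` of the daylight plateau,
#'   seconds since midnight.
#' @param day_level,night_level template levels in lux (night <= day).
#' @param template `"rectangular"` or `"sinusoidal"` (half-sine over the
#'   photoperiod on top of the night level).
#' @param noise_sd sd of the multiplicative log-normal noise applied to
#'   (value + 1); 0 reproduces the template exactly.
#' @param n_gaps wear gaps per participant (rows removed).
#' @param gap_epochs length-2 integer range of gap lengths, in epochs.
#' @param gap_window optional `c(start, end)` seconds-since-midnight band
#'   that gaps must fall inside (e.g. restrict gaps to the night).
#' @param diary `NULL`, or `list(bed, rise, jitter)` in seconds since
#'   midnight / seconds of uniform jitter, for the sleep-diary table.
#' @param seed integer seed; the scenario is fully reproducible under it.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(n_ids = 3, days = 7, epoch = 60,
                          start = "2024-03-04", tz = "UTC",
                          photoperiod = c(8, 18) * 3600,
                          day_level = 1000, night_level = 1,
                          template = c("rectangular", "sinusoidal"),
                          noise_sd = 0.25,
                          n_gaps = 3, gap_epochs = c(5, 30),
                          gap_window = NULL,
                          diary = list(bed = 23 * 3600, rise = 7 * 3600,
                                       jitter = 1800),
                          seed = 1) {
  template <- match.arg(template)
  if (day_level < 0 || night_level < 0) abort("levels must be nonnegative")
  if (night_level > day_level) abort("night level must not exceed day level")
  structure(list(n_ids = n_ids, days = days, epoch = epoch, start = start,
                 tz = tz, photoperiod = photoperiod, day_level = day_level,
                 night_level = night_level, template = template,
                 noise_sd = noise_sd, n_gaps = n_gaps,
                 gap_epochs = gap_epochs, gap_window = gap_window,
                 diary = diary, seed = seed),
            class = "scenario_spec")
}

template_values <- function(sc, tod) {
  inside <- tod >= sc$photoperiod[1] & tod < sc$photoperiod[2]
  if (sc$template == "rectangular") {
    ifelse(inside, sc$day_level, sc$night_level)
  } else {
    span <- sc$photoperiod[2] - sc$photoperiod[1]
    lift <- sin(pi * (tod - sc$photoperiod[1]) / span)
    ifelse(inside,
           sc$night_level + (sc$day_level - sc$night_level) * lift,
           sc$night_level)
  }
}

# non-overlapping gap index runs, optionally confined to a clock window
draw_gaps <- function(sc, tod, n_epochs) {
  lens <- sample(sc$gap_epochs[1]:sc$gap_epochs[2], sc$n_gaps,
                 replace = TRUE)
  taken <- logical(n_epochs)
  gaps <- list()
  for (len in lens) {
    cand <- seq_len(n_epochs - len + 1)
    ok <- vapply(cand, function(i) !any(taken[i:(i + len - 1)]), logical(1))
    if (!is.null(sc$gap_window)) {
      w <- sc$gap_window
      intod <- if (w[1] <= w[2]) tod >= w[1] & tod < w[2]
               else tod >= w[1] | tod < w[2]
      ok <- ok & vapply(cand, function(i) all(intod[i:(i + len - 1)]),
                        logical(1))
    }
    cand <- cand[ok]
    if (!length(cand)) next
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    taken[i:(i + len - 1)] <- TRUE
    gaps[[length(gaps) + 1]] <- c(start = i, len = len)
  }
  gaps
}

#' Generate a ground-truthed synthetic dataset
#'
#' @param sc a [scenario_spec()].
#' @return A list:
#'   * `series`: named list of [light_series] (one per id), with rows
#'     removed where gaps were placed;
#'   * `intervals`: sleep-diary tibble (`Id`, `State`, `Start`, `End`),
#'     or `NULL`;
#'   * `truth`: the generator's own record -- `gaps` (per-id gap table,
#'     same shape as [find_gaps()] output), `daily_dose` (per id and
#'     local day, the noise-free template dose in lx*h over the epochs
#'     actually emitted) and `pulse_blocks` (per id and day, the daylight
#'     plateau intervals remaining after gap removal; rectangular
#'     template only);
#'   * `scenario`: the spec itself.
#' @export
generate_scenario <- function(sc = scenario_spec()) {
  set.seed(sc$seed)
  t0 <- as.POSIXct(paste(sc$start, "00:00:00"), tz = sc$tz)
  n_epochs <- round(sc$days * 86400 / sc$epoch)
  grid <- t0 + (seq_len(n_epochs) - 1) * sc$epoch
  tod <- time_of_day(grid)
  dates <- local_date(grid)
  tmpl <- template_values(sc, tod)

  series <- list()
  truth_gaps <- list()
  truth_dose <- list()
  truth_pulses <- list()
  intervals <- list()
  for (k in seq_len(sc$n_ids)) {
    id <- sprintf("P%02d", k)
    v <- tmpl
    if (sc$noise_sd > 0) {
      v <- pmax((tmpl + 1) * exp(rnorm(n_epochs, 0, sc$noise_sd)) - 1, 0)
    }
    gaps <- draw_gaps(sc, tod, n_epochs)
    gone <- logical(n_epochs)
    for (gp in gaps) gone[gp["start"]:(gp["start"] + gp["len"] - 1)] <- TRUE
    series[[id]] <- light_series(grid[!gone], v[!gone], id = id,
                                 channel = "MEDI", epoch = sc$epoch)
    truth_gaps[[id]] <- if (length(gaps)) {
      g <- do.call(rbind, gaps)
      g <- g[order(g[, "start"]), , drop = FALSE]
      tibble::tibble(
        Id = id, Start = grid[g[, "start"]],
        End = grid[g[, "start"]] + g[, "len"] * sc$epoch,
        Duration = g[, "len"] * sc$epoch, Epochs = as.integer(g[, "len"]))
    } else {
      tibble::tibble(Id = character(), Start = grid[0], End = grid[0],
                     Duration = numeric(), Epochs = integer())
    }
    # noise-free template dose over the epochs actually emitted
    dtab <- tapply(ifelse(gone, 0, tmpl), dates, sum) * sc$epoch / 3600
    truth_dose[[id]] <- tibble::tibble(
      Id = id, Day = as.Date(names(dtab)), Dose = as.numeric(dtab))
    if (sc$template == "rectangular") {
      day_mask <- tmpl >= sc$day_level & !gone
      r <- rle(day_mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      w <- which(r$values)
      truth_pulses[[id]] <- tibble::tibble(
        Id = id,
        Day = dates[starts[w]],
        Onset = grid[starts[w]],
        Offset = grid[ends[w]],
        Epochs = as.integer(r$lengths[w]))
    }
    if (!is.null(sc$diary)) {
      for (d in seq_len(sc$days)) {
        bed <- t0 + (d - 1) * 86400 + sc$diary$bed +
          stats::runif(1, -sc$diary$jitter, sc$diary$jitter)
        rise <- t0 + d * 86400 + sc$diary$rise +
          stats::runif(1, -sc$diary$jitter, sc$diary$jitter)
        intervals[[length(intervals) + 1]] <- tibble::tibble(
          Id = id, State = "sleep", Start = bed, End = rise)
      }
    }
  }
  list(
    series = series,
    intervals = if (length(intervals)) dplyr::bind_rows(intervals) else NULL,
    truth = list(
      gaps = dplyr::bind_rows(truth_gaps),
      daily_dose = dplyr::bind_rows(truth_dose),
      pulse_blocks = dplyr::bind_rows(truth_pulses)
    ),
    scenario = sc
  )
}

# ---- per-dialect fixture files ---------------------------------------------

fixture_number <- function(v, decimal_mark) {
  s <- vapply(v, function(x) {
    if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE,
                                 trim = TRUE)
  }, character(1))
  if (decimal_mark != ".") s <- gsub(".", decimal_mark, s, fixed = TRUE)
  s
}

fixture_timestamp <- function(t, dialect) {
  dt <- dialect$datetime
  policy <- dt$timezone %||% "supplied"
  if (policy == "unix") {
    list(format(as.numeric(t), scientific = FALSE, trim = TRUE))
  } else if (policy == "unix_ms") {
    list(format(as.numeric(t) * 1000, scientific = FALSE, trim = TRUE))
  } else {
    fmts <- unlist(dt$format)
    lapply(fmts, function(f) format(t, f))
  }
}

#' Write a device-dialect fixture file for a series
#'
#' Emits a file conforming to the named device's registered dialect, so
#' the import machinery can be exercised without any real export.
#' Re-importing the fixture reproduces the series exactly (timestamps,
#' values, id).
#'
#' @param series a [light_series]; its first channels map onto the
#'   dialect's channels in order (missing channels are zero-filled).
#' @param device registered device name.
#' @param path output file path.
#' @param registry dialect registry.
#' @param corrupt_rows number of data rows whose timestamp is replaced
#'   with garbage, to exercise drop counting on import.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(series, device, path,
                          registry = device_registry(), corrupt_rows = 0) {
  if (!device %in% names(registry)) {
    abort(sprintf("unknown device '%s'; supported devices are: %s",
                  device, paste(list_supported_devices(registry),
                                collapse = ", ")))
  }
  dialect <- registry[[device]]
  n <- nrow(series)
  cols <- list()
  col_names <- character()
  ts <- fixture_timestamp(series$Datetime, dialect)
  for (j in seq_along(dialect$datetime$columns)) {
    cols[[length(cols) + 1]] <- ts[[j]]
    col_names <- c(col_names, as.character(dialect$datetime$columns[[j]]))
  }
  if (!is.null(dialect$id_column)) {
    cols[[length(cols) + 1]] <- rep(series_id(series), n)
    col_names <- c(col_names, dialect$id_column)
  }
  src <- series_channels(series)
  for (j in seq_along(dialect$channels)) {
    v <- if (j <= length(src)) series[[src[j]]] else rep(0, n)
    cols[[length(cols) + 1]] <- fixture_number(v, dialect$decimal_mark)
    col_names <- c(col_names, dialect$channels[[j]]$column)
  }
  if (corrupt_rows > 0 && n > 0) {
    bad <- sample(n, min(corrupt_rows, n))
    cols[[1]][bad] <- "##corrupt##"
  }
  lines <- character()
  if (dialect$skip > 0) {
    lines <- sprintf("# %s export preamble line %d", dialect$device,
                     seq_len(dialect$skip))
  }
  if (isTRUE(dialect$header)) {
    lines <- c(lines, paste(col_names, collapse = dialect$delimiter))
  }
  if (n > 0) {
    body <- do.call(paste, c(cols, sep = dialect$delimiter))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
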