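#' Find implicit gaps in a light-exposure series
#'
#' Wearable exports drop rows during non-wear or charging, leaving gaps
#' that exist only implicitly as missing grid instants. `find_gaps()`
#' returns every maximal run of grid instants absent from the series.
#'
#' @param x a `light_series` with an inferable epoch.
#' @param epoch grid interval in seconds; defaults to the series epoch.
#' @return A tibble with one row per gap: `Id`, `Start` (first missing
#'   instant), `End` (exclusive, `Start + Duration`), `Duration` in
#'   seconds, `Epochs` (number of missing epochs). Gaps are ordered and
#'   non-overlapping by construction.
#' @export
find_gaps <- function(x, epoch = series_epoch(x)) {
  empty <- tibble::tibble(
    Id = character(), Start = x$Datetime[0], End = x$Datetime[0],
    Duration = numeric(), Epochs = integer()
  )
  n <- nrow(x)
  if (n <= 1) return(empty)
  t <- x$Datetime
  offs <- as.numeric(t) - as.numeric(t[1])
  k <- round(offs / epoch)
  present <- logical(k[n] + 1)
  present[k + 1] <- TRUE
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  miss <- which(!r$values)
  if (!length(miss)) return(empty)
  gap_start <- t[1] + (starts[miss] - 1) * epoch
  dur <- r$lengths[miss] * epoch
  tibble::tibble(
    Id = series_id(x), Start = gap_start, End = gap_start + dur,
    Duration = dur, Epochs = as.integer(r$lengths[miss])
  )
}

#' Fill implicit gaps
#'
#' Completes the epoch grid and fills the inserted rows according to a
#' policy. All inserted rows are flagged in a logical `filled` provenance
#' column so downstream code can always tell observation from fill.
#'
#' @param x a `light_series`.
#' @param policy `"missing"` inserts explicit `NA` rows (the default:
#'   gaps become visible but are never invented data); `"zero"` fills
#'   light channels with 0; `"locf"` carries the last observation forward.
#' @param max_span for `"locf"`, the longest span (seconds) carried into a
#'   gap; epochs beyond it stay missing. A gap at the series start has no
#'   prior observation and always stays missing.
#' @param epoch grid interval in seconds.
#' @return A `light_series` on the complete grid with a `filled` column.
#' @export
fill_gaps <- function(x, policy = c("missing", "zero", "locf"),
                      max_span = Inf, epoch = series_epoch(x)) {
  policy <- match.arg(policy)
  r <- regularize(x, epoch)
  inserted <- !(r$Datetime %in% x$Datetime)
  chans <- series_channels(x)
  if (policy == "zero") {
    for (ch in chans) r[[ch]][inserted] <- 0
  } else if (policy == "locf") {
    max_epochs <- if (is.finite(max_span)) floor(max_span / epoch) else Inf
    runs <- rle(inserted)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (j in which(runs$values)) {
      if (starts[j] == 1) next  # gap at series start: nothing to carry
      take <- starts[j]:min(ends[j], starts[j] + max_epochs - 1)
      if (!length(take) || max_epochs < 1) next
      for (ch in chans) r[[ch]][take] <- r[[ch]][starts[j] - 1]
    }
  }
  r$filled <- inserted
  r
}

#' Aggregate a series to a coarser epoch
#'
#' Windows are anchored at local midnight (so day-based metrics line up
#' with clock time), numeric channels are combined by `fn` (mean by
#' default), and categorical columns such as a state channel by their
#' modal value. A window whose values are all missing stays missing.
#'
#' @param x a `light_series`.
#' @param target_epoch new interval in seconds; must be a multiple of the
#'   current epoch and at least as long.
#' @param fn summary function for numeric channels, applied to the
#'   non-missing values of each window.
#' @return A `light_series` at `target_epoch`.
#' @export
aggregate_epochs <- function(x, target_epoch, fn = mean) {
  ep <- series_epoch(x)
  if (is.na(ep)) abort("series has no epoch")
  ratio <- target_epoch / ep
  if (target_epoch < ep || abs(ratio - round(ratio)) > 1e-8) {
    abort("target_epoch must be an integer multiple of the series epoch")
  }
  if (nrow(x) == 0) return(ls_rebuild(x, x, epoch = target_epoch))
  tod <- time_of_day(x$Datetime)
  win_start <- lubridate::floor_date(x$Datetime, "day") +
    (tod %/% target_epoch) * target_epoch
  grp <- match(win_start, unique(win_start))
  agg_num <- function(v) {
    unname(vapply(split(v, grp), function(w) {
      w <- w[!is.na(w)]
      if (!length(w)) NA_real_ else fn(w)
    }, numeric(1)))
  }
  agg_mode <- function(v) {
    unname(vapply(split(v, grp), function(w) {
      w <- w[!is.na(w)]
      if (!length(w)) return(NA_character_)
      tab <- table(w)
      names(tab)[which.max(tab)]
    }, character(1)))
  }
  out <- tibble::tibble(Datetime = unique(win_start))
  for (col in setdiff(names(x), "Datetime")) {
    out[[col]] <- if (is.numeric(x[[col]])) agg_num(x[[col]])
                  else if (is.logical(x[[col]])) agg_num(as.numeric(x[[col]])) > 0
                  else agg_mode(as.character(x[[col]]))
  }
  ls_rebuild(x, out, epoch = target_epoch)
}

#' Filter a series by date and time of day
#'
#' Both ranges are closed at the start and open at the end, matching the
#' epoch-start attribution of timestamps. The time-of-day range may wrap
#' midnight (e.g. 22:00--06:00).
#'
#' @param x a `light_series`.
#' @param date_range length-2 `Date` (or coercible) vector
#'   `[from, to)`; `NULL` keeps all dates.
#' @param tod_range length-2 numeric seconds-since-midnight `[from, to)`;
#'   `from > to` selects the wrap-around band. `NULL` keeps all times.
#' @return The filtered `light_series` (possibly empty).
#' @export
filter_time <- function(x, date_range = NULL, tod_range = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(date_range)) {
    d <- local_date(x$Datetime)
    date_range <- as.Date(date_range)
    keep <- keep & d >= date_range[1] & d < date_range[2]
  }
  if (!is.null(tod_range)) {
    tod <- time_of_day(x$Datetime)
    keep <- keep & if (tod_range[1] <= tod_range[2]) {
      tod >= tod_range[1] & tod < tod_range[2]
    } else {
      tod >= tod_range[1] | tod < tod_range[2]
    }
  }
  ls_rebuild(x, x[keep, , drop = FALSE])
}

#' Annotate a series with states from an interval table
#'
#' Joins a sleep diary (or any interval table) onto the series: every
#' epoch is labelled with the state of the interval covering its start
#' instant. Intervals are closed at the start and open at the end, and
#' must not overlap within an id -- overlapping diary entries are user
#' errors, never silently resolved.
#'
#' @param x a `light_series`.
#' @param intervals tibble with columns `State`, `Start`, `End`
#'   (`POSIXct`), optionally `Id` (rows for other ids are ignored).
#' @param default_state label for epochs covered by no interval.
#' @param state_col name of the added column.
#' @return The series with an added character state column.
#' @export
interval_to_state <- function(x, intervals, default_state = "none",
                              state_col = "State") {
  iv <- tibble::as_tibble(intervals)
  if ("Id" %in% names(iv)) iv <- iv[iv$Id == series_id(x), , drop = FALSE]
  if (any(iv$Start >= iv$End)) abort("intervals must have Start < End")
  iv <- iv[order(iv$Start), , drop = FALSE]
  if (nrow(iv) >= 2) {
    olap <- which(utils::head(iv$End, -1) > iv$Start[-1])
    if (length(olap)) {
      i <- olap[1]
      abort(sprintf(
        "overlapping intervals: [%s, %s) '%s' overlaps [%s, %s) '%s'",
        format(iv$Start[i]), format(iv$End[i]), iv$State[i],
        format(iv$Start[i + 1]), format(iv$End[i + 1]), iv$State[i + 1]
      ))
    }
  }
  state <- rep(default_state, nrow(x))
  if (nrow(iv) > 0 && nrow(x) > 0) {
    pos <- findInterval(as.numeric(x$Datetime), as.numeric(iv$Start))
    hit <- pos > 0 & as.numeric(x$Datetime) < as.numeric(iv$End)[pmax(pos, 1)]
    state[hit] <- as.character(iv$State)[pos[hit]]
  }
  out <- x
  out[[state_col]] <- state
  ls_rebuild(x, out)
}

#' Join several series into one multi-channel series
#'
#' Outer-joins on the timestamp after aggregating every input to the
#' coarsest common epoch (finer series are averaged into the coarser
#' windows). Channel name collisions are suffixed with the source id.
#' Typical use: combining personal exposure with an environmental
#' daylight-availability reference on one grid.
#'
#' @param series_list list of `light_series` sharing a timezone.
#' @return A single multi-channel `light_series` on the union grid;
#'   instants absent from a source carry `NA` in its channels.
#' @export
join_series <- function(series_list) {
  if (!length(series_list)) abort("need at least one series")
  if (length(series_list) == 1) return(series_list[[1]])
  eps <- vapply(series_list, series_epoch, numeric(1))
  target <- max(eps)
  series_list <- lapply(series_list, function(s) {
    if (series_epoch(s) < target) aggregate_epochs(s, target) else s
  })
  ids <- vapply(series_list, series_id, character(1))
  all_chans <- unlist(lapply(series_list, series_channels))
  dup <- unique(all_chans[duplicated(all_chans)])
  grid <- sort(unique(do.call(c, lapply(series_list, function(s) s$Datetime))))
  out <- tibble::tibble(Datetime = grid)
  chan_names <- character()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    ix <- match(as.numeric(grid), as.numeric(s$Datetime))
    for (ch in series_channels(s)) {
      nm <- if (ch %in% dup) paste0(ch, ".", ids[i]) else ch
      out[[nm]] <- s[[ch]][ix]
      chan_names <- c(chan_names, nm)
    }
  }
  id <- if (length(unique(ids)) == 1) ids[1] else paste(ids, collapse = "+")
  new_light_series(out, id = id, epoch = target, channels = chan_names)
}
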