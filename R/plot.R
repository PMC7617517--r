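#' Day-faceted light exposure plot
#'
#' One facet per local date, time of day on the x axis and light level on
#' a log10 y axis. Light data contain true zeros, which have no place on
#' a log axis; values below `floor` (default 1 lx) are drawn at the
#' floor, and the axis labels the floor tick as "<= floor". Optional
#' interval shading (e.g. sleep-diary states) draws one translucent span
#' per interval row per date.
#'
#' @param x a [light_series].
#' @param intervals optional interval tibble (`Id`, `State`, `Start`,
#'   `End`); rows for other ids are ignored.
#' @param channel light channel to draw; defaults to the first.
#' @param floor lower display bound in lux.
#' @return A ggplot object.
#' @export
day_plot <- function(x, intervals = NULL, channel = NULL, floor = 1) {
  if (nrow(x) == 0) abort("cannot plot an empty series")
  channel <- channel %||% series_channels(x)[1]
  dat <- tibble::tibble(
    Date = local_date(x$Datetime),
    tod = time_of_day(x$Datetime) / 3600,
    value = pmax(series_values(x, channel), floor)
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$tod, y = .data$value))
  if (!is.null(intervals)) {
    iv <- tibble::as_tibble(intervals)
    if ("Id" %in% names(iv)) iv <- iv[iv$Id == series_id(x), , drop = FALSE]
    shade <- day_shading(iv, unique(dat$Date), series_tz(x))
    if (nrow(shade)) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     fill = .data$State),
        ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE)
    }
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_log10(
      name = sprintf("%s (lx, floored at %g)", channel, floor)) +
    ggplot2::scale_x_continuous(
      name = "Local time of day (h)", breaks = seq(0, 24, 6),
      limits = c(0, 24), expand = c(0, 0)) +
    ggplot2::facet_wrap(~Date, ncol = 1) +
    ggplot2::theme_minimal()
}

# clip intervals to each local date; returns one rect row per
# (interval, date) overlap, x in hours since that date's midnight
day_shading <- function(intervals, dates, tz) {
  out <- list()
  for (d in as.list(dates)) {
    d0 <- as.POSIXct(paste(d, "00:00:00"), tz = tz)
    d1 <- d0 + 86400
    for (i in seq_len(nrow(intervals))) {
      a <- max(intervals$Start[i], d0)
      b <- min(intervals$End[i], d1)
      if (a < b) {
        out[[length(out) + 1]] <- tibble::tibble(
          Date = d,
          xmin = as.numeric(a - d0, units = "secs") / 3600,
          xmax = as.numeric(b - d0, units = "secs") / 3600,
          State = as.character(intervals$State[i]))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(Date = as.Date(character()), xmin = numeric(),
                          xmax = numeric(), State = character()))
  }
  dplyr::bind_rows(out)
}
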