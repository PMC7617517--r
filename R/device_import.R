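# ---- device dialect registry -----------------------------------------------
#
# Each supported wearable is described by a declarative dialect (one YAML
# file under inst/extdata/dialects): delimiter, preamble lines to skip,
# header flag, the timestamp column(s) and format, decimal mark, timezone
# policy and the light channels. The parsing machinery below is generic;
# the dialect files are data.

validate_dialect <- function(d, file = "<dialect>") {
  need <- c("device", "manufacturer", "delimiter", "skip", "header",
            "decimal_mark", "datetime", "channels")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(sprintf("dialect %s is missing fields: %s", file,
                  paste(miss, collapse = ", ")))
  }
  dt <- d$datetime
  if (is.null(dt$columns) || !length(dt$columns)) {
    abort(sprintf("dialect %s: exactly one timestamp role required", file))
  }
  if (!length(d$channels)) {
    abort(sprintf("dialect %s: at least one light channel required", file))
  }
  d$requires_preprocessing <- isTRUE(d$requires_preprocessing)
  d
}

#' Registry of supported device dialects
#'
#' Reads every dialect YAML shipped with the package (or found in `dir`)
#' into a named list. Device names are unique within a registry.
#'
#' The dialect layouts are declarative configurations exercised against
#' generated fixture files; faithfulness to the proprietary exports of
#' each vendor is deferred until real sample files are available.
#'
#' @param dir directory of dialect YAML files; defaults to the set
#'   shipped with the package.
#' @return Named list of dialect definitions.
#' @export
device_registry <- function(dir = NULL) {
  dir <- dir %||% system.file("extdata", "dialects", package = "luxmetrics")
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (!length(files)) abort(sprintf("no dialect files found in %s", dir))
  dialects <- lapply(files, function(f) {
    validate_dialect(yaml::read_yaml(f), basename(f))
  })
  nms <- vapply(dialects, function(d) d$device, character(1))
  if (anyDuplicated(nms)) abort("device names must be unique in the registry")
  stats::setNames(dialects, nms)
}

#' Names of devices with a registered import dialect
#'
#' @param registry a dialect registry from [device_registry()].
#' @return Character vector of device names, sorted.
#' @export
list_supported_devices <- function(registry = device_registry()) {
  sort(names(registry))
}

# ---- parsing ----------------------------------------------------------------

# resolve a dialect column reference against a header (or positionally)
resolve_col <- function(col, header_names) {
  if (is.null(header_names)) return(as.integer(col))
  i <- match(col, header_names)
  if (is.na(i)) abort(sprintf("column '%s' not found in file header", col))
  i
}

parse_timestamps <- function(str, dialect, tz) {
  dt <- dialect$datetime
  fmt <- paste(unlist(dt$format), collapse = " ")
  policy <- dt$timezone %||% "supplied"
  if (policy == "unix") {
    out <- as.POSIXct(suppressWarnings(as.numeric(str)),
                      origin = "1970-01-01", tz = tz)
  } else if (policy == "unix_ms") {
    out <- as.POSIXct(suppressWarnings(as.numeric(str)) / 1000,
                      origin = "1970-01-01", tz = tz)
  } else if (policy == "embedded") {
    # offset in the string defines the instant; represent in the supplied zone
    out <- strptime(str, fmt, tz = "UTC")
    out <- lubridate::with_tz(as.POSIXct(out), tz)
  } else {
    out <- as.POSIXct(strptime(str, fmt, tz = tz))
  }
  out
}

parse_device_file <- function(path, dialect, tz, id_pattern) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > dialect$skip) {
    lines <- lines[(dialect$skip + 1):length(lines)]
  } else {
    lines <- character()
  }
  header_names <- NULL
  if (isTRUE(dialect$header) && length(lines)) {
    header_names <- strsplit(lines[1], dialect$delimiter, fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  parsed <- length(lines)
  dropped <- c(malformed = 0L, bad_timestamp = 0L)
  empty_row <- function() {
    out <- tibble::tibble(Id = character(),
                          Datetime = as.POSIXct(character(), tz = tz))
    for (ch in dialect$channels) out[[ch$channel]] <- numeric()
    out
  }
  if (parsed == 0) {
    return(list(rows = empty_row(), parsed = 0L, dropped = dropped))
  }
  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  nf <- lengths(fields)
  expected <- max(nf)
  ok <- nf == expected
  dropped["malformed"] <- sum(!ok)
  fields <- fields[ok]
  if (!length(fields)) {
    return(list(rows = empty_row(), parsed = parsed, dropped = dropped))
  }
  mat <- do.call(rbind, fields)

  dt_cols <- vapply(dialect$datetime$columns, resolve_col,
                    integer(1), header_names)
  ts_str <- if (length(dt_cols) == 1) mat[, dt_cols] else {
    do.call(paste, lapply(dt_cols, function(j) mat[, j]))
  }
  ts <- parse_timestamps(ts_str, dialect, tz)
  ok <- !is.na(ts)
  dropped["bad_timestamp"] <- sum(!ok)

  ids <- if (!is.null(dialect$id_column)) {
    mat[, resolve_col(dialect$id_column, header_names)]
  } else {
    m <- regmatches(basename(path), regexpr(id_pattern, basename(path)))
    rep(if (length(m)) m else basename(path), nrow(mat))
  }
  out <- tibble::tibble(Id = ids[ok], Datetime = ts[ok])
  for (ch in dialect$channels) {
    raw <- mat[ok, resolve_col(ch$column, header_names)]
    raw <- gsub(dialect$decimal_mark, ".", raw, fixed = TRUE)
    v <- suppressWarnings(as.numeric(raw))
    v[!is.na(v) & v < 0] <- NA_real_  # negative light is sensor garbage
    out[[ch$channel]] <- v
  }
  list(rows = out, parsed = parsed, dropped = dropped)
}

#' Import device export files into light series
#'
#' Reads one or more files written by a supported wearable, using the
#' device's registered dialect, and returns one [light_series] per
#' detected id plus an import report. The id comes from an in-file
#' column when the dialect declares one, otherwise from the filename via
#' `id_pattern`. Rows with unparseable timestamps are dropped and
#' counted; duplicate timestamps within an id keep the first occurrence.
#'
#' @param paths file paths; all must exist.
#' @param device device name; must be registered (see
#'   [list_supported_devices()]).
#' @param tz IANA timezone applied to timestamps without an embedded
#'   offset, and used to represent all timestamps.
#' @param id_pattern regular expression extracting the id from the file
#'   basename when the dialect has no id column.
#' @param registry dialect registry.
#' @param preprocessed assert that externally required preprocessing
#'   (e.g. GGIR for GENEActiv) has been applied; without it such devices
#'   refuse to import.
#' @return A list with `series` (named list of `light_series`) and
#'   `report` (an `import_report`).
#' @export
import_files <- function(paths, device, tz = "UTC",
                         id_pattern = "^[A-Za-z0-9]+",
                         registry = device_registry(),
                         preprocessed = FALSE) {
  if (!device %in% names(registry)) {
    abort(sprintf(
      "unknown device '%s'; supported devices are: %s",
      device, paste(list_supported_devices(registry), collapse = ", ")))
  }
  dialect <- registry[[device]]
  if (dialect$requires_preprocessing && !preprocessed) {
    abort(sprintf(
      paste("device '%s' exports raw data that must be preprocessed",
            "externally (e.g. with GGIR) before import; rerun with",
            "preprocessed = TRUE once that is done"), device))
  }
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    abort(paste("file not found:", missing_files[1]))
  }
  parts <- lapply(paths, parse_device_file, dialect = dialect, tz = tz,
                  id_pattern = id_pattern)
  rows <- dplyr::bind_rows(lapply(parts, `[[`, "rows"))
  parsed <- sum(vapply(parts, `[[`, integer(1), "parsed"))
  dropped <- Reduce(`+`, lapply(parts, `[[`, "dropped"))
  if (parsed > 0 && sum(dropped) > 0.5 * parsed) {
    abort(sprintf("%d of %d rows failed to parse for device '%s'",
                  sum(dropped), parsed, device))
  }
  rows <- rows[order(rows$Id, rows$Datetime), , drop = FALSE]
  dup <- duplicated(rows[, c("Id", "Datetime")])
  dropped <- c(dropped, duplicate_timestamp = sum(dup))
  rows <- rows[!dup, , drop = FALSE]

  chans <- vapply(dialect$channels, function(ch) ch$channel, character(1))
  series <- lapply(split(rows, rows$Id), function(r) {
    light_series(r$Datetime, r[, chans, drop = FALSE], id = r$Id[1])
  })
  if (!length(series) && is.null(dialect$id_column) && length(paths) == 1) {
    # header-only file: an empty series under the filename id
    m <- regmatches(basename(paths), regexpr(id_pattern, basename(paths)))
    id <- if (length(m)) m else basename(paths)
    series <- stats::setNames(
      list(light_series(as.POSIXct(character(), tz = tz), numeric(),
                        id = id, channel = chans[1], epoch = NA)), id)
  }
  diffs <- unlist(lapply(series, function(s) diff(as.numeric(s$Datetime))))
  report <- structure(list(
    device = device,
    files = paths,
    rows_parsed = parsed,
    rows_emitted = nrow(rows),
    rows_dropped = tibble::tibble(reason = names(dropped),
                                  count = as.integer(dropped)),
    epoch = vapply(series, series_epoch, numeric(1)),
    ids = names(series),
    time_range = if (nrow(rows)) range(rows$Datetime) else NULL,
    interval_histogram = if (length(diffs)) table(diffs) else table(numeric())
  ), class = "import_report")
  list(series = series, report = report)
}

#' @export
print.import_report <- function(x, ...) {
  cat(sprintf("<import_report> device: %s | %d file(s)\n",
              x$device, length(x$files)))
  cat(sprintf("  rows: %d parsed = %d emitted + %d dropped\n",
              x$rows_parsed, x$rows_emitted, sum(x$rows_dropped$count)))
  drp <- x$rows_dropped[x$rows_dropped$count > 0, ]
  if (nrow(drp)) {
    cat(sprintf("    dropped: %s\n",
                paste(sprintf("%s=%d", drp$reason, drp$count),
                      collapse = ", ")))
  }
  cat(sprintf("  ids: %s\n", paste(x$ids, collapse = ", ")))
  if (!is.null(x$time_range)) {
    cat(sprintf("  span: %s -- %s\n", format(x$time_range[1]),
                format(x$time_range[2])))
  }
  invisible(x)
}

# ---- canonical on-disk form -------------------------------------------------

#' Read and write the canonical tidy CSV form
#'
#' The package's own interchange format: one row per epoch with columns
#' `Id`, `Datetime` (ISO-8601 with offset) and one column per light
#' channel; missing values are empty fields.
#'
#' @param series a `light_series` or list of them.
#' @param path CSV file path.
#' @param tz timezone for the returned series.
#' @return `write_light_csv()` returns `path` invisibly;
#'   `read_light_csv()` a named list of `light_series`.
#' @export
write_light_csv <- function(series, path) {
  if (inherits(series, "light_series")) series <- list(series)
  rows <- dplyr::bind_rows(lapply(series, function(s) {
    out <- tibble::as_tibble(s)
    out$Datetime <- format(out$Datetime, "%Y-%m-%dT%H:%M:%S%z")
    dplyr::bind_cols(tibble::tibble(Id = series_id(s)), out)
  }))
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

#' @rdname write_light_csv
#' @export
read_light_csv <- function(path, tz = "UTC") {
  dat <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(Id = readr::col_character(),
                            Datetime = readr::col_character(),
                            .default = readr::col_guess()))
  dat$Datetime <- lubridate::with_tz(
    as.POSIXct(strptime(dat$Datetime, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")), tz)
  lapply(split(dat, dat$Id), function(r) {
    vals <- r[, setdiff(names(r), c("Id", "Datetime")), drop = FALSE]
    light_series(r$Datetime, vals, id = r$Id[1])
  })
}

#' Read and write interval tables
#'
#' Interval tables (sleep diaries and similar) travel as CSV with
#' columns `Id`, `State`, `Start`, `End` in ISO-8601 with offset.
#'
#' @param intervals tibble with columns `Id`, `State`, `Start`, `End`.
#' @param path CSV path.
#' @param tz timezone for the returned instants.
#' @return `read_interval_csv()` returns the interval tibble.
#' @export
write_interval_csv <- function(intervals, path) {
  out <- tibble::as_tibble(intervals)
  out$Start <- format(out$Start, "%Y-%m-%dT%H:%M:%S%z")
  out$End <- format(out$End, "%Y-%m-%dT%H:%M:%S%z")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_interval_csv
#' @export
read_interval_csv <- function(path, tz = "UTC") {
  dat <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(Start = readr::col_character(),
                            End = readr::col_character(),
                            .default = readr::col_guess()))
  parse <- function(s) {
    lubridate::with_tz(
      as.POSIXct(strptime(s, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")), tz)
  }
  dat$Start <- parse(dat$Start)
  dat$End <- parse(dat$End)
  dat
}
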