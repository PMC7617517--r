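# shared fixtures: quick series construction on a regular grid

T0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")

mk_series <- function(values, epoch = 60, start = T0, id = "P1",
                      channel = "lux") {
  light_series(start + epoch * (seq_along(values) - 1), values,
               id = id, channel = channel, epoch = epoch)
}

# one full day at a given epoch from a function of seconds-since-midnight
mk_day <- function(f, epoch = 3600, start = T0, id = "P1") {
  n <- 86400 / epoch
  tod <- epoch * (0:(n - 1))
  mk_series(f(tod), epoch = epoch, start = start, id = id)
}

# rectangular day: `level` lux inside [from, to) seconds, `base` outside
rect_day <- function(from, to, level = 1000, base = 0, epoch = 3600,
                     start = T0) {
  mk_day(function(tod) ifelse(tod >= from & tod < to, level, base),
         epoch = epoch, start = start)
}

# independent O(n^2) pulse oracle: a valid span is a pair (i, j) of
# qualifying epochs whose interior interruptions are all <= max_interrupt;
# pulses are the maximal valid spans lasting at least min_duration
pulse_oracle <- function(mask, epoch, min_duration, max_interrupt) {
  mask[is.na(mask)] <- FALSE
  n <- length(mask)
  valid <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!mask[i]) next
    run_gap <- 0
    for (j in i:n) {
      if (mask[j]) {
        run_gap <- 0
        valid[i, j] <- TRUE
      } else {
        run_gap <- run_gap + epoch
        if (run_gap > max_interrupt) break
      }
    }
  }
  spans <- which(valid, arr.ind = TRUE)
  if (!nrow(spans)) return(spans)
  is_max <- apply(spans, 1, function(p) {
    i <- p[1]; j <- p[2]
    left <- i > 1 && any(valid[seq_len(i - 1), j])
    right <- j < n && any(valid[i, (j + 1):n])
    !left && !right
  })
  maximal <- spans[is_max, , drop = FALSE]
  maximal <- maximal[order(maximal[, 1]), , drop = FALSE]
  keep <- (maximal[, 2] - maximal[, 1] + 1) * epoch >= min_duration
  maximal[keep, , drop = FALSE]
}
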