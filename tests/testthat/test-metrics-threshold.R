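test_that("durations are qualifying-epoch counts times the epoch", {
  s <- mk_series(c(0, 300, 300, 0, 300, 0))
  expect_equal(duration_above_threshold(s, 250)$Value, 180)
  expect_equal(duration_above_threshold(s, 250, "below")$Value, 180)
  expect_equal(duration_above_threshold(s, c(0, 400), "within")$Value, 360)
  expect_error(duration_above_threshold(mk_series(numeric(0)), 250),
               "empty")
})

test_that("timing above threshold averages qualifying epoch-start times", {
  v <- rep(0, 24); v[c(10, 12)] <- 500  # epochs starting 09:00 and 11:00
  s <- mk_series(v, epoch = 3600)
  expect_equal(timing_above_threshold(s, 250)$Value, 10 * 3600)
  none <- timing_above_threshold(s, 9999)
  expect_true(is.na(none$Value))
  expect_match(none$Reason, "no epochs")
})

test_that("timing matches an arithmetic-mean oracle on random days", {
  set.seed(5)
  v <- rep(0, 1440)
  qualifying <- sample(1440, 100)
  v[qualifying] <- 300
  s <- mk_series(v, epoch = 60)
  oracle <- mean((qualifying - 1) * 60)
  expect_equal(timing_above_threshold(s, 250)$Value, oracle)
})

test_that("circular and arithmetic timing agree away from midnight", {
  v <- rep(0, 24); v[c(11, 15)] <- 500
  s <- mk_series(v, epoch = 3600)
  expect_equal(timing_above_threshold(s, 250, circular = TRUE)$Value,
               timing_above_threshold(s, 250)$Value, tolerance = 1e-9)
})

test_that("longest period bridges interruptions up to max_interrupt", {
  s <- mk_series(c(0, 1, 1, 1, 0, 1) * 300)
  expect_equal(period_above_threshold(s, 250)$Value, 3 * 60)
  expect_equal(period_above_threshold(s, 250, max_interrupt = 60)$Value,
               5 * 60)
  all_on <- mk_series(rep(300, 7))
  expect_equal(period_above_threshold(all_on, 250)$Value, 7 * 60)
})

test_that("crossing counts equal brute-force transition counts", {
  s <- mk_series(c(0, 300, 0, 300, 0))
  expect_equal(frequency_crossing_threshold(s, 250)$Value, 4)
  expect_equal(frequency_crossing_threshold(mk_series(rep(9, 5)), 250)$Value,
               0)
  set.seed(2)
  v <- sample(c(0, 500), 300, replace = TRUE)
  s2 <- mk_series(v)
  mask <- v >= 250
  oracle <- sum(mask[-1] != mask[-length(mask)])
  expect_equal(frequency_crossing_threshold(s2, 250)$Value, oracle)
})

test_that("threshold_for_duration returns the k-th order statistic", {
  s <- mk_series(c(10, 100, 1000))
  expect_equal(threshold_for_duration(s, 60)$Value, 1000)
  expect_equal(threshold_for_duration(s, 120)$Value, 100)
  expect_equal(threshold_for_duration(s, 60, "below")$Value, 10)
  expect_error(threshold_for_duration(s, 600), "exceeds")
})

test_that("duration_above(threshold_for_duration(d)) >= d on random series", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(20:100, 1)
    s <- mk_series(round(rlnorm(n, 3, 2), 3))
    d <- sample(n, 1) * 60
    thr <- threshold_for_duration(s, d)$Value
    expect_gte(duration_above_threshold(s, thr)$Value, d)
    # the next larger distinct level no longer sustains d
    larger <- sort(unique(s$lux[s$lux > thr]))
    if (length(larger)) {
      expect_lt(duration_above_threshold(s, larger[1])$Value, d)
    }
  }
})

test_that("pulse statistics follow the onset/offset conventions", {
  # one block 10:00-12:00 above threshold at 5-min epochs
  s <- rect_day(10 * 3600, 12 * 3600, level = 1000, base = 0, epoch = 300)
  res <- pulses_above_threshold(s, 250, min_duration = 1800,
                                max_interrupt = 0)
  val <- function(m) res$Value[res$Metric == paste0("pulses_above_", m)]
  expect_equal(val("count"), 1)
  expect_equal(val("mean_onset"), 10 * 3600)
  expect_equal(val("mean_midpoint"), 11 * 3600)
  expect_equal(val("mean_offset"), 12 * 3600 - 300)
  expect_equal(val("total_duration"), 2 * 3600)
  expect_equal(val("mean_level"), 1000)

  # all below threshold: count 0, others undefined
  res0 <- pulses_above_threshold(mk_series(rep(0, 100)), 250)
  expect_equal(res0$Value[res0$Metric == "pulses_above_count"], 0)
  expect_true(all(is.na(res0$Value[res0$Metric != "pulses_above_count"])))
})

test_that("interruptions shorter than max_interrupt merge into one pulse", {
  v <- c(rep(400, 10), rep(0, 2), rep(400, 10))  # 2-epoch interruption
  s <- mk_series(v, epoch = 60)
  res <- pulses_above_threshold(s, 250, min_duration = 300,
                                max_interrupt = 120)
  val <- function(m) res$Value[res$Metric == paste0("pulses_above_", m)]
  expect_equal(val("count"), 1)
  expect_equal(val("total_duration"), 22 * 60)  # interruption included
  res2 <- pulses_above_threshold(s, 250, min_duration = 300,
                                 max_interrupt = 60)
  expect_equal(res2$Value[res2$Metric == "pulses_above_count"], 2)
})

test_that("pulse detection equals the brute-force oracle on random series", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(20:200, 1)
    v <- sample(c(0, 0, 500, 800), n, replace = TRUE)
    s <- mk_series(v, epoch = 60)
    min_d <- sample(c(120, 300, 600), 1)
    max_i <- sample(c(0, 60, 180), 1)
    spans <- luxmetrics:::merge_runs(v >= 250, 60, max_i)
    spans <- spans[(spans$end - spans$start + 1) * 60 >= min_d, ]
    oracle <- pulse_oracle(v >= 250, 60, min_d, max_i)
    expect_equal(nrow(spans), nrow(oracle))
    if (nrow(spans)) {
      expect_equal(spans$start, unname(oracle[, 1]))
      expect_equal(spans$end, unname(oracle[, 2]))
    }
    res <- pulses_above_threshold(s, 250, min_duration = min_d,
                                  max_interrupt = max_i)
    expect_equal(res$Value[res$Metric == "pulses_above_count"], nrow(oracle))
  }
})

test_that("threshold metrics are scale equivariant", {
  set.seed(6)
  v <- round(rlnorm(200, 4, 1.5), 4)
  s <- mk_series(v)
  s10 <- mk_series(v * 10)
  for (mode in c("above", "below")) {
    expect_equal(duration_above_threshold(s10, 2500, mode)$Value,
                 duration_above_threshold(s, 250, mode)$Value)
    expect_equal(timing_above_threshold(s10, 2500, mode)$Value,
                 timing_above_threshold(s, 250, mode)$Value)
    expect_equal(period_above_threshold(s10, 2500, mode)$Value,
                 period_above_threshold(s, 250, mode)$Value)
  }
  p1 <- pulses_above_threshold(s, 250)
  p10 <- pulses_above_threshold(s10, 2500)
  tim <- grepl("onset|midpoint|offset|count|duration", p1$Metric)
  expect_equal(p1$Value[tim], p10$Value[tim])
})

test_that("timing metrics shift with the clock", {
  v <- rep(0, 24); v[c(9, 13)] <- 600
  s <- mk_series(v, epoch = 3600)
  s_shift <- light_series(s$Datetime + 2 * 3600, v, epoch = 3600)
  expect_equal(timing_above_threshold(s_shift, 250)$Value,
               timing_above_threshold(s, 250)$Value + 2 * 3600)
})
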