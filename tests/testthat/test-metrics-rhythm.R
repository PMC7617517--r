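test_that("brightest/darkest windows land on the plateau, ties earliest", {
  s <- rect_day(8 * 3600, 18 * 3600, level = 1000, base = 0, epoch = 600)
  res <- bright_dark_period(s, "brightest", window = 10 * 3600)
  val <- function(m) res$Value[res$Metric == paste0("brightest_", m)]
  expect_equal(val("mean"), 1000)
  expect_equal(val("onset"), 8 * 3600)
  expect_equal(val("offset"), 18 * 3600 - 600)
  expect_equal(val("midpoint"), 13 * 3600)

  # constant day: earliest window wins the tie
  cst <- mk_series(rep(7, 288), epoch = 300)
  r2 <- bright_dark_period(cst, "darkest", window = 5 * 3600)
  expect_equal(r2$Value[r2$Metric == "darkest_onset"], 0)
})

test_that("looped windows wrap across midnight", {
  # bright block 21:00-07:00 (wraps); 10-h window must start at 21:00
  s <- mk_day(function(tod) ifelse(tod >= 21 * 3600 | tod < 7 * 3600,
                                   900, 0), epoch = 1800)
  res <- bright_dark_period(s, "brightest", window = 10 * 3600, loop = TRUE)
  expect_equal(res$Value[res$Metric == "brightest_onset"], 21 * 3600)
  expect_equal(res$Value[res$Metric == "brightest_mean"], 900)
  # brute force over all circular windows
  v <- s$lux
  k <- 20
  means <- vapply(seq_along(v), function(i) {
    mean(c(v, v)[i:(i + k - 1)])
  }, numeric(1))
  expect_equal(res$Value[res$Metric == "brightest_mean"], max(means))
})

test_that("centroid of exposure is the exposure-weighted mean clock time", {
  sym <- mk_day(function(tod) 1000 * exp(-((tod - 12 * 3600) / 7200)^2),
                epoch = 600)
  expect_equal(centroid_of_exposure(sym)$Value, 12 * 3600, tolerance = 1e-9)
  one <- mk_day(function(tod) ifelse(tod == 15 * 3600, 800, 0), epoch = 300)
  expect_equal(centroid_of_exposure(one)$Value, 15 * 3600)
  set.seed(4)
  v <- rlnorm(288, 3, 2)
  s <- mk_series(v, epoch = 300)
  tod <- time_of_day(s$Datetime)
  expect_equal(centroid_of_exposure(s)$Value, sum(tod * v) / sum(v))
  dark <- mk_series(rep(0, 10))
  expect_true(is.na(centroid_of_exposure(dark)$Value))
})

test_that("midpoint of cumulative exposure uses the earliest >= half rule", {
  one <- mk_day(function(tod) ifelse(tod == 15 * 3600, 800, 0), epoch = 300)
  expect_equal(midpoint_cumulative_exposure(one)$Value, 15 * 3600)
  unif <- mk_series(rep(10, 24), epoch = 3600)
  expect_equal(midpoint_cumulative_exposure(unif)$Value, 11 * 3600)
  set.seed(4)
  v <- rlnorm(288, 3, 2)
  s <- mk_series(v, epoch = 300)
  i <- which(cumsum(v) >= sum(v) / 2)[1]
  expect_equal(midpoint_cumulative_exposure(s)$Value, (i - 1) * 300)
})

test_that("interdaily stability is 1 for identical repeated days", {
  day <- rlnorm(24, 4, 1)
  s <- mk_series(rep(day, 2), epoch = 3600)
  expect_equal(interdaily_stability(s)$Value, 1, tolerance = 1e-12)
  cst <- mk_series(rep(5, 48), epoch = 3600)
  r <- interdaily_stability(cst)
  expect_true(is.na(r$Value))
  expect_match(r$Reason, "zero variance")
})

test_that("IS on i.i.d. noise matches a direct-formula simulation oracle", {
  is_oracle <- function(v, p = 24) {
    h <- rep(seq_len(p), length.out = length(v))
    xb <- mean(v)
    length(v) * sum((tapply(v, h, mean) - xb)^2) / (p * sum((v - xb)^2))
  }
  set.seed(100)
  impl <- oracle <- numeric(200)
  for (r in 1:200) {
    v <- rlnorm(240, 3, 1)  # 10 days hourly
    impl[r] <- interdaily_stability(mk_series(v, epoch = 3600))$Value
    oracle[r] <- is_oracle(v)
  }
  expect_equal(impl, oracle, tolerance = 1e-12)
  # mean IS of iid noise stays within 3 SE of the simulated oracle mean
  se <- sd(oracle) / sqrt(length(oracle))
  expect_lt(abs(mean(impl) - mean(oracle)), 3 * se + 1e-12)
  expect_true(all(impl >= 0 & impl <= 1 + 1e-9))
})

test_that("intradaily variability is exactly 4 for even alternation", {
  s <- mk_series(rep(c(100, 600), 24), epoch = 3600)
  expect_equal(intradaily_variability(s)$Value, 4, tolerance = 1e-12)
  cst <- mk_series(rep(5, 48), epoch = 3600)
  expect_true(is.na(intradaily_variability(cst)$Value))
})

test_that("IV matches the direct formula on a multi-day sinusoid", {
  tod <- rep(3600 * (0:23), 10)
  v <- 500 + 400 * sin(2 * pi * tod / 86400)
  s <- mk_series(v, epoch = 3600)
  n <- length(v)
  oracle <- n * sum(diff(v)^2) / ((n - 1) * sum((v - mean(v))^2))
  expect_equal(intradaily_variability(s)$Value, oracle, tolerance = 1e-12)
  expect_gte(oracle, 0)
})

test_that("exponential smoothing honours its half-life definition", {
  cst <- mk_series(rep(42, 50))
  expect_equal(series_values(exponential_moving_average(cst), "lux_ema"),
               rep(42, 50))
  # unit step: half the step height is reached one half-life in
  half_life <- 3600
  v <- c(rep(0, 10), rep(1, 120))
  s <- mk_series(v, epoch = 60)
  sm <- series_values(exponential_moving_average(s, half_life), "lux_ema")
  at <- 10 + half_life / 60  # one half-life's worth of epochs past the step
  expect_equal(sm[at], 0.5, tolerance = 1e-10)
  expect_lt(abs(sm[at + 1] - 0.5), 0.01)  # within one-epoch discretization
})

test_that("smoothing equals the unrolled recursion and skips missing", {
  set.seed(12)
  v <- rlnorm(100, 3, 1)
  v[c(20, 21, 50)] <- NA
  s <- mk_series(v)
  lambda <- 1 - 2^(-60 / 1800)
  state <- NA_real_
  oracle <- rep(NA_real_, 100)
  for (i in 1:100) {
    if (is.na(v[i])) next
    state <- if (is.na(state)) v[i] else lambda * v[i] + (1 - lambda) * state
    oracle[i] <- state
  }
  sm <- series_values(exponential_moving_average(s, 1800), "lux_ema")
  expect_equal(sm, oracle)
  expect_true(all(is.na(sm[c(20, 21, 50)])))
})

test_that("disparity index is the mean absolute log step", {
  expect_equal(disparity_index(mk_series(rep(123, 30)))$Value, 0)
  expect_equal(disparity_index(mk_series(c(0, exp(1) - 1)))$Value, 1)
  set.seed(8)
  v <- rlnorm(200, 3, 1)
  expect_equal(disparity_index(mk_series(v))$Value,
               mean(abs(diff(log(v + 1)))))
})

test_that("dose integrates lux-hours", {
  expect_equal(dose(mk_series(rep(1000, 60), epoch = 60))$Value, 1000)
  expect_equal(dose(mk_series(rep(0, 60)))$Value, 0)
})

test_that("Barroso percentile metrics behave on two-level days", {
  cstv <- rep(50, 48)
  cst <- mk_series(cstv, epoch = 3600)  # two constant days
  res <- barroso_metrics(cst)
  val <- function(m) res$Value[res$Metric == m]
  expect_equal(val("bright_threshold"), 50)
  expect_equal(val("dark_threshold"), 50)
  expect_equal(val("bright_cluster"), 24 * 3600)
  expect_equal(val("dark_cluster"), 24 * 3600)
  expect_equal(val("circadian_variation"), 0)

  # ~10% of the day at 1000 lx: the interpolated 90th percentile falls
  # strictly between the two levels, so the bright mean is exactly 1000
  v <- rep(0, 24); v[12:14] <- 1000
  day2 <- mk_series(v, epoch = 3600)
  r2 <- barroso_metrics(day2)
  expect_equal(r2$Value[r2$Metric == "bright_mean_level"], 1000)

  # circadian variation equals the sd/mean oracle across days
  set.seed(30)
  v3 <- rlnorm(24 * 5, 3, 1)
  s3 <- mk_series(v3, epoch = 3600)
  daily <- colMeans(matrix(v3, 24))
  r3 <- barroso_metrics(s3)
  expect_equal(r3$Value[r3$Metric == "circadian_variation"],
               sd(daily) / mean(daily))
})
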