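test_that("find_gaps recovers maximal runs of absent grid instants", {
  s <- light_series(T0 + c(0, 60, 240, 300), c(1, 1, 1, 1), epoch = 60)
  g <- find_gaps(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$Epochs, 2L)
  expect_equal(as.numeric(g$Start), as.numeric(T0) + 120)
  expect_equal(as.numeric(g$End), as.numeric(T0) + 240)
  expect_equal(g$Duration, g$Epochs * 60)

  expect_equal(nrow(find_gaps(mk_series(1:10))), 0)
})

test_that("find_gaps recovers the generator's gap truth exactly", {
  sc <- generate_scenario(scenario_spec(n_ids = 1, days = 3, n_gaps = 3,
                                        seed = 7))
  g <- find_gaps(sc$series[[1]])
  truth <- sc$truth$gaps
  expect_equal(nrow(g), 3)
  expect_equal(as.numeric(g$Start), as.numeric(truth$Start))
  expect_equal(g$Epochs, truth$Epochs)
})

test_that("fill_gaps policies behave as documented and flag provenance", {
  s <- light_series(T0 + c(0, 60, 240, 300), c(5, 6, 7, 8), epoch = 60)
  fm <- fill_gaps(s, "missing")
  expect_equal(nrow(fm), 6)
  expect_equal(fm$lux, c(5, 6, NA, NA, 7, 8))
  expect_equal(fm$filled, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(find_gaps(fm)), 0)

  fz <- fill_gaps(s, "zero")
  expect_equal(fz$lux, c(5, 6, 0, 0, 7, 8))

  # locf limited to one epoch: first gap epoch copied, second stays missing
  fl <- fill_gaps(s, "locf", max_span = 60)
  expect_equal(fl$lux, c(5, 6, 6, NA, 7, 8))
  # unlimited locf carries across the whole gap
  expect_equal(fill_gaps(s, "locf")$lux, c(5, 6, 6, 6, 7, 8))
})

test_that("locf never invents data before the first observation", {
  s <- light_series(T0 + c(120, 180), c(1, 2), epoch = 60)
  r <- regularize(s, 60)
  expect_equal(nrow(r), 2)  # grid starts at first observation
  # leading gap created by joining onto an earlier series stays missing
  s2 <- light_series(T0 + c(0, 240, 300), c(9, 1, 2), epoch = 60)
  fl <- fill_gaps(s2, "locf", max_span = 60)
  expect_equal(fl$lux, c(9, 9, NA, NA, 1, 2))
})

test_that("aggregation averages within midnight-anchored windows", {
  s <- mk_series(rep(100, 60), epoch = 60)
  h <- aggregate_epochs(s, 3600)
  expect_equal(nrow(h), 1)
  expect_equal(h$lux, 100)

  s2 <- mk_series(0:59, epoch = 60)
  expect_equal(aggregate_epochs(s2, 3600)$lux, 29.5)

  # windows anchor at local midnight, not at the first sample
  s3 <- light_series(T0 + 1800 + 60 * (0:59), rep(1, 60), epoch = 60)
  h3 <- aggregate_epochs(s3, 3600)
  expect_equal(time_of_day(h3$Datetime), c(0, 3600))

  # all-missing window stays missing
  s4 <- mk_series(c(rep(NA_real_, 60), rep(2, 60)), epoch = 60)
  expect_equal(aggregate_epochs(s4, 3600)$lux, c(NA, 2))
})

test_that("aggregation conserves dose on complete windows", {
  set.seed(21)
  s <- mk_series(runif(2880) * 5000, epoch = 30)  # one full day at 30 s
  d0 <- dose(s)$Value
  for (target in c(300, 3600, 7200)) {
    expect_equal(dose(aggregate_epochs(s, target))$Value, d0,
                 tolerance = 1e-9)
  }
})

test_that("filter_time keeps closed-start open-end ranges, wrapping ok", {
  s <- mk_day(function(tod) rep(1, length(tod)), epoch = 3600)
  expect_equal(nrow(filter_time(s, tod_range = c(8, 20) * 3600)), 12)
  expect_equal(nrow(filter_time(s, tod_range = c(22, 6) * 3600)), 8)
  expect_equal(nrow(filter_time(s, tod_range = c(5, 5) * 3600)), 0)
  expect_equal(nrow(filter_time(s, date_range = c("2024-03-02",
                                                  "2024-03-03"))), 0)
})

test_that("interval_to_state labels by epoch start, half-open", {
  s <- mk_day(function(tod) rep(1, length(tod)), epoch = 3600)
  iv <- tibble::tibble(
    Id = "P1", State = "sleep",
    Start = T0 + 23 * 3600, End = T0 + 31 * 3600)
  lab <- interval_to_state(s, iv)
  expect_equal(lab$State[24], "sleep")   # 23:00 epoch is covered
  expect_equal(lab$State[23], "none")
  # instant exactly at End gets the default (open end)
  s2 <- light_series(T0 + 31 * 3600, 1, epoch = 3600)
  expect_equal(interval_to_state(s2, iv)$State, "none")
})

test_that("overlapping intervals are an error naming the first overlap", {
  s <- mk_series(1:5)
  iv <- tibble::tibble(Id = "P1", State = c("a", "b"),
                       Start = T0 + c(0, 100), End = T0 + c(200, 300))
  expect_error(interval_to_state(s, iv), "overlapping intervals")
})

test_that("state labels agree with a point-in-interval scan", {
  set.seed(3)
  s <- mk_series(runif(500), epoch = 60)
  # randomized non-overlapping intervals
  cuts <- sort(sample(0:500, 20)) * 60
  iv <- tibble::tibble(
    Id = "P1",
    State = sample(letters[1:4], 10, replace = TRUE),
    Start = T0 + cuts[seq(1, 20, 2)],
    End = T0 + cuts[seq(2, 20, 2)])
  lab <- interval_to_state(s, iv)$State
  # O(n*m) oracle: check every epoch against every interval
  oracle <- vapply(s$Datetime, function(t) {
    hit <- which(t >= iv$Start & t < iv$End)
    if (length(hit)) iv$State[hit[1]] else "none"
  }, character(1))
  expect_equal(lab, oracle)
})

test_that("joining series aligns grids and suffixes colliding channels", {
  personal <- mk_series(rep(100, 48), epoch = 1800, id = "P1")
  daylight <- mk_series(rep(5000, 24), epoch = 3600, id = "daylight")
  j <- join_series(list(personal, daylight))
  expect_equal(series_epoch(j), 3600)
  expect_setequal(series_channels(j), c("lux.P1", "lux.daylight"))
  expect_equal(nrow(j), 24)
  expect_equal(j[["lux.P1"]], rep(100, 24))

  # disjoint ranges produce the union grid with missing blocks
  a <- mk_series(rep(1, 4), epoch = 60, id = "A")
  b <- mk_series(rep(2, 4), epoch = 60, start = T0 + 600, id = "B")
  jj <- join_series(list(a, b))
  expect_equal(nrow(jj), 8)
  expect_equal(sum(is.na(jj$lux.A)), 4)

  # join then split recovers the originals on their own grid
  back <- jj[!is.na(jj$lux.A), c("Datetime", "lux.A")]
  expect_equal(back$lux.A, a$lux)
  expect_equal(as.numeric(back$Datetime), as.numeric(a$Datetime))
})
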