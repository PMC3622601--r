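test_that("an exact frame-aligned template copy scores 1 at the planted time", {
  tpl <- song_template()
  hop <- 64  # 256-sample window at 75% overlap
  fs <- 2000
  wave <- numeric(fs * 120)
  off <- hop * 500
  wave[off + seq_along(tpl$waveform)] <- tpl$waveform
  ev <- detect_template(wave, tpl, fs = fs, threshold = 0.9)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$score, 1, tolerance = 1e-9)
  planted_center <- off / fs + tpl$duration / 2
  expect_lt(abs(ev$time - planted_center), 3 * hop / fs)
})

test_that("two planted copies 60 s apart yield two events 60 s apart", {
  tpl <- song_template()
  fs <- 2000
  wave <- numeric(fs * 180)
  offs <- c(64 * 500, 64 * 500 + 60 * fs)
  for (off in offs) wave[off + seq_along(tpl$waveform)] <- tpl$waveform
  ev <- detect_template(wave, tpl, fs = fs, threshold = 0.9)
  expect_equal(nrow(ev), 2L)
  expect_equal(diff(ev$time), 60, tolerance = 0.1)
})

test_that("pure noise at a high threshold produces no events", {
  tpl <- song_template()
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    ev <- detect_template(rnorm(2000 * 20), tpl, threshold = 0.9)
    hits <- hits + nrow(ev)
  }
  expect_equal(hits, 0L)
})

test_that("raising the threshold never increases the event count", {
  tpl <- song_template()
  fs <- 2000
  set.seed(11)
  wave <- rnorm(fs * 120, 0, 0.3)
  for (off in c(20, 50, 80) * fs) {
    wave[off + seq_along(tpl$waveform)] <-
      wave[off + seq_along(tpl$waveform)] + tpl$waveform
  }
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(th) nrow(detect_template(wave, tpl, fs = fs,
                                                     threshold = th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_true(all(detect_template(wave, tpl, fs = fs,
                                  threshold = 0.4)$score >= 0.4))
})

test_that("degenerate detector inputs are rejected", {
  tpl <- song_template()
  empty <- tpl
  empty$S <- tpl$S[, 0, drop = FALSE]
  expect_error(detect_template(rnorm(4000), empty), "empty template")
  expect_error(detect_template(rnorm(100), tpl), "shorter")
})

test_that("presence aggregation counts song-hours per day", {
  start <- as.POSIXct("2009-04-01 00:00:00", tz = "UTC")
  end <- start + 3 * 86400
  ev <- data.frame(time = c(1, 3, 8, 8.5, 13, 20) * 3600 + 30)
  p <- aggregate_presence(ev, start, end)
  expect_equal(p$daily$hours_with_song[1], 5)  # 5 distinct hours on day 1
  expect_equal(sum(p$daily$hours_with_song[-1]), 0)
  expect_true(all(p$daily$hours_with_song >= 0 &
                    p$daily$hours_with_song <= 24))

  # no events -> all-zero series
  p0 <- aggregate_presence(data.frame(time = numeric(0)), start, end)
  expect_true(all(p0$daily$hours_with_song == 0))

  # events at 23:59 and 00:01 fall on two different days, one hour each
  ev2 <- data.frame(time = c(23 * 3600 + 59 * 60, 24 * 3600 + 60))
  p2 <- aggregate_presence(ev2, start, end)
  expect_equal(p2$daily$hours_with_song[1:2], c(1, 1))

  expect_error(aggregate_presence(data.frame(time = 5 * 86400), start, end),
               "calendar")
})

test_that("aggregating an already-hourly series is a no-op", {
  start <- as.POSIXct("2009-04-01 00:00:00", tz = "UTC")
  end <- start + 2 * 86400
  ev <- data.frame(time = c(2, 5, 7, 30) * 3600 + 10)
  p1 <- aggregate_presence(ev, start, end)
  ev_hourly <- data.frame(
    time = (which(p1$hourly$present) - 1) * 3600)
  p2 <- aggregate_presence(ev_hourly, start, end)
  expect_equal(p1$hourly$present, p2$hourly$present)
})

test_that("detector evaluation computes miss and false-alarm rates", {
  start <- as.POSIXct("2009-04-01 00:00:00", tz = "UTC")
  cal <- data.frame(date = "2009-04-01", hour = 0:23,
                    present = rep(FALSE, 24))
  truth <- cal; truth$present[1:10] <- TRUE
  det <- truth; det$present[3] <- FALSE  # miss 1 of 10 song-hours
  r <- evaluate_detector(det, truth)
  expect_equal(r$false_negative_rate, 0.1)
  expect_equal(r$false_positive_rate, 0)

  same <- evaluate_detector(truth, truth)
  expect_equal(same$false_negative_rate, 0)
  expect_equal(same$false_positive_rate, 0)

  # no true song-hours: miss rate undefined
  none <- evaluate_detector(cal, cal)
  expect_true(is.na(none$false_negative_rate))

  other <- cal; other$hour <- c(1:23, 0)
  expect_error(evaluate_detector(other, truth), "calendar")
})
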