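test_that("correlated random walk recovers its nominal speed and step count", {
  trk <- simulate_track(2, duration = 0.5, step_dt = 60, seed = 1)
  expect_equal(nrow(trk), 31L)  # 30 steps -> 31 positions
  expect_true(all(diff(trk$t) == 60))

  # sample mean speed over many steps approaches the nominal value
  long <- simulate_track(2, duration = 10000 / 60, step_dt = 60, seed = 2)
  sm <- step_metrics(long)
  mean_kmh <- mean(sm$distance / sm$dt) * 3.6
  expect_lt(abs(mean_kmh - 2) / 2, 0.02)

  expect_error(simulate_track(-1, 1, 60), "positive")
  expect_error(simulate_track(2, 0, 60), "positive")
})

test_that("infinite turning concentration gives a perfectly straight path", {
  trk <- simulate_track(3, duration = 1, step_dt = 60,
                        turn_concentration = Inf, seed = 7)
  st <- track_stats(trk)
  expect_equal(st$straightness, 1, tolerance = 1e-12)
  expect_equal(st$net_displacement_km, st$distance_km, tolerance = 1e-12)
  # collinearity: all cross products of consecutive steps are zero
  dx <- diff(trk$x); dy <- diff(trk$y)
  cross <- dx[-1] * dy[-length(dy)] - dy[-1] * dx[-length(dx)]
  expect_lt(max(abs(cross)) / max(dx^2 + dy^2), 1e-10)
})

test_that("simulator output is byte-identical under a fixed seed", {
  a <- simulate_track(2, 0.5, 60, seed = 9)
  b <- simulate_track(2, 0.5, 60, seed = 9)
  expect_identical(a, b)
  arr <- small_array()
  cfg <- sim_config(snr_db = 20, source_depth = 50, seed = 4)
  r1 <- render_recording(arr, stationary_track(1000, 500),
                         emission_schedule(2), cfg)
  r2 <- render_recording(arr, stationary_track(1000, 500),
                         emission_schedule(2), cfg)
  expect_identical(r1$wave, r2$wave)
})

test_that("arrivals respect geometry: equal ranges, spreading loss, TDOA", {
  # sensors 1 and 2 are equidistant from the midpoint below
  arr <- small_array()
  u <- render_unit_at(arr, c(2000, 0))
  tr <- u$rec$truth
  expect_equal(tr$arrival_true[tr$channel == 1],
               tr$arrival_true[tr$channel == 2], tolerance = 1e-12)

  # sensor at twice the range receives half the amplitude (exponent 1)
  arr2 <- hydrophone_array(c(1000, 2000, 0), c(0, 0, 1000), rep(50, 3))
  u2 <- render_unit_at(arr2, c(0, 0))
  rms <- sqrt(colMeans(u2$rec$wave^2))
  expect_equal(rms[1] / rms[2], 2, tolerance = 1e-6)

  # cross-correlation peak lag matches the geometric TDOA within 1 sample
  w1 <- u2$rec$wave[, 1]; w2 <- u2$rec$wave[, 2]
  cc <- Re(fft(fft(c(w1, 0 * w1)) * Conj(fft(c(w2, 0 * w2))),
               inverse = TRUE))
  n2 <- 2 * length(w1)
  lags <- c(0:(n2 / 2 - 1), -(n2 / 2):-1)
  peak_lag <- lags[which.max(cc)] / u2$rec$fs
  pred <- predicted_tdoa(c(0, 0), arr2, 1480)[1, 2]
  expect_lt(abs(peak_lag - pred), 1 / u2$rec$fs)
})

test_that("aliasing and out-of-span emissions are rejected", {
  arr <- small_array(sample_rate = 600)
  expect_error(render_recording(arr, stationary_track(0, 0),
                                emission_schedule(2, f0 = 100, f1 = 400),
                                sim_config(snr_db = Inf)),
               "aliasing")
  expect_error(render_recording(small_array(), stationary_track(0, 0, 5),
                                emission_schedule(9),
                                sim_config(snr_db = Inf)),
               "time span")
  expect_error(emission_schedule(2, f0 = 5), "band")
})

test_that("calibration playbacks log every sweep and are reproducible", {
  arr <- small_array()
  pos <- data.frame(x = c(1000, 2500), y = c(500, -800))
  cfg <- sim_config(snr_db = Inf, source_depth = 50, seed = 3)
  pb <- simulate_calibration_playbacks(arr, pos, 5, cfg)
  expect_equal(nrow(pb$log), 10L)
  expect_equal(as.integer(table(pb$log$position)), c(5L, 5L))
  pb2 <- simulate_calibration_playbacks(arr, pos, 5, cfg)
  expect_identical(pb$recordings[[1]]$wave, pb2$recordings[[1]]$wave)
  expect_error(simulate_calibration_playbacks(arr, pos[0, ], 5, cfg),
               "at least one")
})

test_that("clock-drift correction is linear, exact at endpoints, invertible", {
  expect_equal(correct_clock_drift(c(0, 100, 987), 0, 0, 1000),
               c(0, 100, 987))
  # offset grows to 1 s over the deployment: 0.5 s correction at midpoint
  t_true <- 500
  t_rec <- t_true + drift_offset(t_true, 0, 1, 1000)
  expect_equal(t_rec - t_true, 0.5)
  expect_equal(correct_clock_drift(t_rec, 0, 1, 1000), t_true)
  expect_error(drift_offset(1, 0, 1, 0), "span")
})

test_that("drift applied in rendering is corrected to sub-sample accuracy", {
  cs <- data.frame(id = 1:4, offset_start = c(0, 0.1, -0.05, 0.02),
                   offset_end = c(0.5, -0.2, 0.15, -0.3), span = 5000)
  arr <- small_array(clock_sync = cs)
  src <- c(1800, 700)
  u <- render_unit_at(arr, src)
  cc <- unit_ccfs(u$sel[1, ], u$rec)
  m <- songtrack:::measured_peak_lags(cc)
  td <- predicted_tdoa(src, arr, 1480)
  resid <- abs(m$lag - td[cbind(m$i, m$j)])
  expect_lt(max(resid), 1 / u$rec$fs)
})
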