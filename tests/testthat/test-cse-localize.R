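test_that("predicted TDOA follows range differences and is antisymmetric", {
  arr <- hydrophone_array(c(0, 4440, 1000), c(0, 0, 3000), rep(50, 3))
  # candidate 2960 m from sensor 1 and 1480 m from sensor 2 at c = 1480 m/s
  cand <- c(2960, 0)
  td <- predicted_tdoa(cand, arr, 1480)
  expect_equal(td[1, 2], 1.0, tolerance = 1e-12)
  # equidistant candidate: zero delay
  expect_equal(predicted_tdoa(c(2220, 123), arr, 1480)[1, 2], 0,
               tolerance = 1e-12)
  set.seed(1)
  for (k in 1:20) {
    td <- predicted_tdoa(runif(2, -5000, 5000), arr, 1480)
    expect_equal(td, -t(td), tolerance = 1e-12)
  }
})

test_that("correlation sum peaks at the true source and sums to the pair count", {
  arr <- small_array()
  src <- c(1700, -900)
  u <- render_unit_at(arr, src)
  b <- u$sel[1, "Begin Time (s)"]; e <- u$sel[1, "End Time (s)"]
  s_true <- correlation_sum(src, u$rec, b, e)
  expect_gt(s_true, 0.9 * 6)  # 6 pairs, each near-perfectly aligned
  # exhaustive oracle on a small grid: no candidate beats the true location
  g <- as.matrix(expand.grid(x = seq(-1000, 5000, by = 250),
                             y = seq(-4000, 4000, by = 250)))
  s_grid <- correlation_sum(g, u$rec, b, e)
  expect_true(all(s_grid <= s_true + 1e-8))
})

test_that("correlation sum is invariant under a common time shift", {
  arr <- small_array()
  src <- c(1700, -900)
  u <- render_unit_at(arr, src)
  b <- u$sel[1, "Begin Time (s)"]; e <- u$sel[1, "End Time (s)"]
  s1 <- correlation_sum(src, u$rec, b, e)
  shift <- 400  # samples prepended to every channel
  rec2 <- u$rec
  rec2$wave <- rbind(matrix(0, shift, ncol(u$rec$wave)), u$rec$wave)
  s2 <- correlation_sum(src, rec2, b + shift / u$rec$fs,
                        e + shift / u$rec$fs)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-6)
})

test_that("independent noise clips score near zero far from any source", {
  arr <- small_array()
  rec <- render_recording(arr, stationary_track(0, 0, 60),
                          emission_schedule(2),
                          sim_config(snr_db = 0, source_depth = 50,
                                     seed = 8), t_end = 60)
  # a window of pure noise well after the unit has passed every channel
  s <- correlation_sum(c(20000, 20000), rec, 40, 43)
  expect_lt(abs(as.numeric(s)), 0.2 * 6)
})

test_that("a noise-free source at a coarse-grid node is recovered exactly", {
  arr <- small_array()
  grid <- search_grid(arr, margin = 2000, resolution = 200)
  src <- c(grid$xlim[1] + 15 * 200, grid$ylim[1] + 22 * 200)
  u <- render_unit_at(arr, src)
  est <- cse_localize(u$sel[1, ], u$rec, grid = grid)
  expect_equal(c(est$x, est$y), src, tolerance = 1e-9)
  expect_equal(est$qc, "pass")
})

test_that("a source at the centroid of a symmetric array lands at the centroid", {
  arr <- hydrophone_array(c(-2000, 2000, 2000, -2000),
                          c(-2000, -2000, 2000, 2000), rep(50, 4))
  u <- render_unit_at(arr, c(0, 0))
  td <- predicted_tdoa(c(0, 0), arr, 1480)
  expect_true(all(abs(td) < 1e-12))  # all delays vanish by symmetry
  est <- cse_localize(u$sel[1, ], u$rec,
                      grid = search_grid(arr, margin = 2000))
  expect_lt(euclid(c(est$x, est$y), c(0, 0)), 2)
})

test_that("iterative refinement matches the exhaustive fine-grid argmax", {
  arr <- small_array()
  grid <- search_grid(arr, margin = 2000, resolution = 200)
  set.seed(21)
  for (k in 1:5) {
    src <- c(runif(1, 0, 4000), runif(1, -3000, 3000))
    u <- render_unit_at(arr, src)
    cc <- unit_ccfs(u$sel[1, ], u$rec)
    e1 <- cse_localize(u$sel[1, ], u$rec, grid = grid, ccfs = cc)
    e2 <- cse_localize(u$sel[1, ], u$rec, grid = grid, ccfs = cc,
                       method = "exhaustive")
    expect_lte(euclid(c(e1$x, e1$y), c(e2$x, e2$y)), 2)
    expect_lte(euclid(c(e1$x, e1$y), src), 2)
  }
})

test_that("quality control flags lag disagreement and honours its tolerance", {
  arr <- small_array()
  src <- c(1800, 700)
  u <- render_unit_at(arr, src)
  est <- cse_localize(u$sel[1, ], u$rec)
  expect_equal(est$qc, "pass")
  expect_lt(est$qc_residual, 1 / u$rec$fs)  # sub-sample residual, noise-free

  # fabricate one inconsistent pair: QC must fail
  td <- predicted_tdoa(src, arr, 1480)
  meas <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                     lag = c(td[1, 2] + 0.1, td[1, 3], td[2, 3]))
  expect_false(qc_location(src, meas, arr)$pass)
  expect_true(qc_location(src, meas, arr, tolerance = Inf)$pass)
})

test_that("a channel carrying an unrelated unit makes the estimate fail QC", {
  arr <- small_array()
  u <- render_unit_at(arr, c(1800, 700))
  other <- render_unit_at(arr, c(3800, 200))  # near sensor 2
  rec <- u$rec
  n <- min(nrow(rec$wave), nrow(other$rec$wave))
  rec$wave[, 2] <- 0
  rec$wave[seq_len(n), 2] <- other$rec$wave[seq_len(n), 2]
  est <- cse_localize(u$sel[1, ], rec)
  expect_equal(est$qc, "fail")
})

test_that("calibration error is the horizontal distance to the known source", {
  r <- calibration_error(data.frame(x = 30, y = 40),
                         data.frame(x = 0, y = 0))
  expect_equal(r$mean_error, 50)
  r2 <- calibration_error(data.frame(x = c(1, 2), y = c(3, 4)),
                          data.frame(x = c(1, 2), y = c(3, 4)))
  expect_equal(r2$mean_error, 0)
  expect_equal(r2$sd_error, 0)
  expect_error(calibration_error(data.frame(x = numeric(0),
                                            y = numeric(0)),
                                 data.frame(x = 1, y = 1)), "no estimates")
  expect_error(calibration_error(data.frame(x = 1, y = 1),
                                 data.frame(x = c(1, 2), y = c(1, 2))),
               "one known position per estimate")
})

test_that("localization error grows with arrival-time jitter", {
  arr <- small_array()
  src <- c(1500, 1000)
  err_at <- function(jit, seed) {
    u <- render_unit_at(arr, src,
                        cfg = sim_config(snr_db = Inf, source_depth = 50,
                                         arrival_jitter_sd = jit,
                                         seed = seed))
    est <- cse_localize(u$sel[1, ], u$rec, qc_tolerance = Inf)
    euclid(c(est$x, est$y), src)
  }
  e_small <- vapply(1:4, function(s) err_at(0.002, s), numeric(1))
  e_large <- vapply(1:4, function(s) err_at(0.04, s), numeric(1))
  expect_lt(median(e_small), median(e_large))
})
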