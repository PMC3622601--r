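test_that("step metrics: distances, headings and turning angles", {
  sm <- step_metrics(data.frame(t = c(0, 100), x = c(0, 3), y = c(0, 4)))
  expect_equal(sm$distance, 5)
  expect_equal(sm$dt, 100)

  # three collinear points: zero turning angle
  sm2 <- step_metrics(data.frame(t = c(0, 60, 120), x = c(0, 1, 2),
                                 y = c(0, 2, 4)))
  expect_equal(sm2$turning_angle[2], 0, tolerance = 1e-12)

  # east step then north step: +90 degree turn
  sm3 <- step_metrics(data.frame(t = c(0, 60, 120), x = c(0, 1, 1),
                                 y = c(0, 0, 1)))
  expect_equal(sm3$turning_angle[2], pi / 2, tolerance = 1e-12)

  expect_error(step_metrics(data.frame(t = c(0, 0, 60), x = 1:3, y = 1:3)),
               "duplicate")
  # zero-length step: turning angle undefined, flagged, not zero
  sm4 <- step_metrics(data.frame(t = c(0, 60, 120, 180),
                                 x = c(0, 1, 1, 2), y = c(0, 0, 0, 0)))
  expect_true(is.na(sm4$turning_angle[2]))
  expect_gte(attr(sm4, "n_undefined_turns"), 1L)
})

test_that("whole-track statistics match hand-computed fixtures", {
  # straight track: straightness index exactly 1
  straight <- data.frame(t = 0:5 * 600, x = 0:5 * 400, y = 0:5 * 300)
  expect_equal(track_stats(straight)$straightness, 1, tolerance = 1e-12)

  # closed loop: zero net displacement
  loop <- data.frame(t = 0:4 * 60, x = c(0, 1, 1, 0, 0),
                     y = c(0, 0, 1, 1, 0))
  expect_equal(track_stats(loop)$straightness, 0, tolerance = 1e-12)

  # (0,0) -> (1,1) -> (2,0): distance 2*sqrt(2), displacement 2
  tri <- data.frame(t = 0:2 * 60, x = c(0, 1, 2), y = c(0, 1, 0))
  st <- track_stats(tri)
  expect_equal(st$distance_km * 1000, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(st$net_displacement_km * 1000, 2, tolerance = 1e-12)
  expect_equal(st$straightness, 2 / (2 * sqrt(2)), tolerance = 1e-12)

  # 4 km in 2 h -> 2 km/h
  st2 <- track_stats(data.frame(t = c(0, 7200), x = c(0, 4000), y = c(0, 0)))
  expect_equal(st2$speed_kmh, 2, tolerance = 1e-12)

  expect_error(track_stats(data.frame(t = 0, x = 0, y = 0)), "at least 2")
  zl <- track_stats(data.frame(t = c(0, 60), x = c(0, 0), y = c(0, 0)))
  expect_true(is.na(zl$straightness) && zl$zero_length)
})

test_that("track statistics obey their structural invariants", {
  set.seed(41)
  for (k in 1:50) {
    n <- sample(3:30, 1)
    tr <- data.frame(t = cumsum(runif(n, 30, 120)),
                     x = cumsum(rnorm(n, 0, 80)), y = cumsum(rnorm(n, 0, 80)))
    st <- track_stats(tr)
    expect_gte(st$straightness, 0)
    expect_lte(st$straightness, 1)
    expect_lte(st$net_displacement_km, st$distance_km + 1e-12)
    expect_equal(st$speed_kmh * st$duration_h, st$distance_km,
                 tolerance = 1e-12)
    # invariance under rigid rotation + translation
    th <- runif(1, 0, 2 * pi)
    rot <- data.frame(t = tr$t,
                      x = 500 + cos(th) * tr$x - sin(th) * tr$y,
                      y = -900 + sin(th) * tr$x + cos(th) * tr$y)
    str <- track_stats(rot)
    expect_equal(str$distance_km, st$distance_km, tolerance = 1e-9)
    expect_equal(str$straightness, st$straightness, tolerance = 1e-9)
  }
})

test_that("Spearman correlations match the rank-formula oracle", {
  st <- data.frame(session = letters[1:6], season = "spring",
                   duration_h = 1:6, distance_km = (1:6)^2,
                   speed_kmh = c(2, 1, 4, 3, 6, 5),
                   net_displacement_km = 6:1,
                   straightness = rep(0.5, 6))
  cp <- correlate_params(st)
  expect_equal(cp$rho["duration_h", "distance_km"], 1)       # monotone up
  expect_equal(cp$rho["duration_h", "net_displacement_km"], -1)
  expect_true("straightness" %in% cp$constant)
  expect_true(all(is.na(cp$rho["straightness",
                               setdiff(colnames(cp$rho), "straightness")])))

  set.seed(5)
  x <- rnorm(20); y <- rnorm(20)
  st2 <- data.frame(duration_h = x, distance_km = y)
  cp2 <- correlate_params(st2, params = c("duration_h", "distance_km"))
  expect_equal(cp2$rho[1, 2], spearman_oracle(x, y), tolerance = 1e-12)

  expect_error(correlate_params(st[1:2, ]), "at least 3")
})

test_that("seasonal comparison matches the Welch formula oracle", {
  spring <- c(2.81, 1.96, 3.50, 2.20, 1.40, 4.10)
  fall <- c(1.91, 1.38, 2.50, 0.90, 1.10)
  st <- data.frame(season = rep(c("fall", "spring"),
                                c(length(fall), length(spring))),
                   duration_h = c(fall, spring))
  res <- seasonal_compare(st, params = "duration_h")
  w <- res$parameters$duration_h$welch
  o <- welch_oracle(fall, spring)
  expect_equal(w$t, o$t, tolerance = 1e-10)
  expect_equal(w$df, o$df, tolerance = 1e-10)
  expect_equal(w$p, o$p, tolerance = 1e-10)

  # pooled degrees of freedom are n1 + n2 - 2
  expect_equal(res$parameters$duration_h$pooled$df,
               length(spring) + length(fall) - 2)

  # swapping group labels negates t and preserves p
  st2 <- st
  st2$season <- ifelse(st$season == "spring", "a_spring", "b_fall")
  res2 <- seasonal_compare(st2, params = "duration_h")
  expect_equal(res2$parameters$duration_h$welch$t, -w$t, tolerance = 1e-10)
  expect_equal(res2$parameters$duration_h$welch$p, w$p, tolerance = 1e-10)
})

test_that("degenerate seasonal comparisons behave sensibly", {
  # identical groups: t = 0, p = 1
  g <- c(1.2, 3.4, 2.2, 4.0)
  st <- data.frame(season = rep(c("spring", "fall"), each = 4),
                   speed_kmh = c(g, g))
  res <- seasonal_compare(st, params = "speed_kmh")
  expect_equal(res$parameters$speed_kmh$welch$t, 0)
  expect_equal(res$parameters$speed_kmh$welch$p, 1)

  const <- data.frame(season = rep(c("spring", "fall"), each = 3),
                      speed_kmh = rep(2, 6))
  expect_error(seasonal_compare(const, params = "speed_kmh"),
               "zero variance")

  # daily song occurrence compared alongside the track parameters
  pres <- data.frame(season = rep(c("spring", "fall"), each = 20),
                     hours_with_song = c(rpois(20, 9), rpois(20, 3)))
  res2 <- seasonal_compare(st, params = "speed_kmh", presence = pres)
  expect_true(is.finite(res2$presence$t))
})

test_that("two-singer segmentation: separations, partition and kinematics", {
  # parallel straight tracks 1 km apart
  tt <- 0:100 * 60
  a <- data.frame(t = tt, x = tt * 0.5, y = 0)
  b <- data.frame(t = tt, x = tt * 0.5, y = 1000)
  sp <- pair_interaction(a, b, overlap = c(1800, 4200))
  expect_equal(sp$separation_start_km, 1, tolerance = 1e-12)
  expect_equal(sp$separation_end_km, 1, tolerance = 1e-12)
  # straight segments have SI = 1
  expect_equal(sp$singer_a$both$straightness, 1, tolerance = 1e-9)
  expect_equal(sp$singer_a$alone$straightness, 1, tolerance = 1e-9)

  # singer A doubles speed during the overlap
  v <- 2 / 3.6  # 2 km/h in m/s
  t_seg <- 0:120 * 60
  xa <- ifelse(t_seg <= 3600, v * t_seg,
               v * 3600 + 2 * v * (t_seg - 3600))
  a2 <- data.frame(t = t_seg, x = xa, y = 0)
  b2 <- data.frame(t = t_seg, x = 2000 + v * t_seg, y = 3000)
  sp2 <- pair_interaction(a2, b2, overlap = c(3600, 7200))
  expect_equal(sp2$singer_a$both$speed_kmh /
                 sp2$singer_a$alone$speed_kmh, 2, tolerance = 1e-9)

  expect_error(pair_interaction(a, b, c(-10, 100)), "within")
})
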