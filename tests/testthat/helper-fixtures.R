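# Shared fixtures: arrays, single-unit scenes, and small oracles.

# Compact 4-sensor array for fast unit tests (flat bathymetry so slant and
# horizontal ranges coincide and noise-free localization is exact).
small_array <- function(depth = 50, clock_sync = NULL, sample_rate = 2000) {
  hydrophone_array(x = c(0, 4000, 2000, 2000),
                   y = c(0, 0, 3500, -3500),
                   depth = rep(depth, 4),
                   sample_rate = sample_rate, clock_sync = clock_sync)
}

# Ten-sensor array with nearest-neighbour spacing 6 km (within the 3-6 nmi
# deployment spacing), flat bathymetry at 60 m.
ten_array <- function(depth = 60) {
  hydrophone_array(
    x = c(0, 6000, 12000, 3000, 9000, 0, 6000, 12000, 3000, 9000),
    y = c(0, 0, 0, 5200, 5200, 10400, 10400, 10400, 15600, 15600),
    depth = rep(depth, 10))
}

# Six-sensor array with varied sensor depths, used for the calibration
# experiment (slant-range bias becomes part of the measured error).
cal_array <- function() {
  hydrophone_array(x = c(0, 6000, 12000, 1500, 7500, 3000),
                   y = c(0, 0, 0, 5200, 5200, 10400),
                   depth = c(40, 60, 80, 100, 55, 70))
}

# A stationary source "track" at a fixed position.
stationary_track <- function(x, y, t_end = 10) {
  structure(data.frame(t = c(0, t_end), x = rep(x, 2), y = rep(y, 2)),
            class = c("source_track", "data.frame"))
}

# Render a single sweep unit from `src` and return the recording plus its
# selection table.
render_unit_at <- function(array, src, cfg = sim_config(snr_db = Inf,
                                                        source_depth = 50),
                           t_emit = 2, duration = 1.5) {
  rec <- render_recording(array, stationary_track(src[1], src[2]),
                          emission_schedule(t_emit, duration = duration),
                          cfg)
  list(rec = rec, sel = selections_from_truth(rec))
}

# Uniform draw from (an inset of) the ten-sensor array's convex hull.
runif_in_hull <- function(n, inset = 500) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    x <- runif(2 * n, inset, 12000 - inset)
    y <- runif(2 * n, inset, 15600 - inset)
    # hull edges above y = 10400 slope inward; below is the full rectangle
    ok_right <- x <= 12000 - pmax(0, y - 10400) * 3000 / 5200 - inset
    ok_left <- x >= pmax(0, y - 10400) * 3000 / 5200 + inset
    keep <- ok_right & ok_left
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Independent Welch t-test oracle (textbook formulas).
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Independent Spearman oracle for untied data: 1 - 6*sum(d^2)/(n(n^2-1)).
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
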