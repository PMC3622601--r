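#' Simulate a singer's movement path as a correlated random walk
#'
#' Generates a ground-truth source track with the movement variation seen in
#' tracked singers — from highly meandering to highly directional — using a
#' correlated random walk: successive headings differ by wrapped-normal
#' turning angles with standard deviation `1 / sqrt(turn_concentration)`, and
#' per-step speeds are gamma-distributed with mean `nominal_speed`.
#' `turn_concentration = Inf` gives a perfectly straight path.
#'
#' @param nominal_speed Mean swimming speed in km/h; must be positive.
#' @param duration Track duration in hours.
#' @param step_dt Time step in seconds.
#' @param turn_concentration Dimensionless concentration of the turning-angle
#'   distribution; larger is straighter. `Inf` means no turning.
#' @param speed_shape Shape of the gamma step-speed distribution (mean is
#'   always `nominal_speed`); larger means less speed variability.
#' @param start Starting position `c(x, y)` in meters.
#' @param heading0 Initial heading in radians; random if `NULL`.
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @return A `source_track`: data frame with columns `t` (s), `x`, `y` (m),
#'   plus attributes `nominal_speed` and `turn_concentration`.
#' @examples
#' trk <- simulate_track(2, duration = 0.5, step_dt = 60, seed = 1)
#' nrow(trk)  # 31 positions for 30 steps
#' @export
simulate_track <- function(nominal_speed, duration, step_dt,
                           turn_concentration = 5, speed_shape = 8,
                           start = c(0, 0), heading0 = NULL, seed = NULL) {
  stop_if_not_positive(nominal_speed, "nominal_speed")
  stop_if_not_positive(duration, "duration")
  stop_if_not_positive(step_dt, "step_dt")
  if (turn_concentration <= 0) {
    stop("`turn_concentration` must be positive (Inf allowed)", call. = FALSE)
  }
  n <- round(duration * 3600 / step_dt)
  if (n < 1L) stop("duration must cover at least one step", call. = FALSE)
  v <- nominal_speed * KMH_TO_MS
  with_seed(seed, {
    h0 <- if (is.null(heading0)) stats::runif(1, 0, 2 * pi) else heading0
    turns <- if (is.infinite(turn_concentration)) {
      rep(0, n - 1L)
    } else {
      wrap_angle(stats::rnorm(n - 1L, 0, 1 / sqrt(turn_concentration)))
    }
    headings <- h0 + cumsum(c(0, turns))
    speeds <- stats::rgamma(n, shape = speed_shape, rate = speed_shape / v)
    steps <- speeds * step_dt
    out <- data.frame(
      t = seq(0, by = step_dt, length.out = n + 1L),
      x = start[1] + c(0, cumsum(steps * cos(headings))),
      y = start[2] + c(0, cumsum(steps * sin(headings))))
    structure(out, nominal_speed = nominal_speed,
              turn_concentration = turn_concentration,
              class = c("source_track", "data.frame"))
  })
}

#' Simulation configuration
#'
#' Physical and numerical settings shared by the rendering functions.
#' Propagation is straight-ray at a single constant sound speed, with
#' power-law spreading loss `r^-spreading_exponent` (exponent 1 = spherical
#' spreading). Ambient noise is white Gaussian band-limited to `band` and
#' scaled so that a unit at `ref_range` from a source of `ref_source_level`
#' dB re 1 uPa has the requested SNR; `snr_db = Inf` disables noise.
#'
#' @param sound_speed Sound speed in m/s.
#' @param snr_db Signal-to-noise ratio in dB at `ref_range`; `Inf` = no noise.
#' @param ref_range Reference range in meters for the SNR definition.
#' @param ref_source_level Source level (dB re 1 uPa at 1 m) used as the SNR
#'   reference.
#' @param spreading_exponent Geometric spreading-loss exponent.
#' @param band Noise band in Hz (matches the recorder's flat response band).
#' @param source_depth Depth (m) at which the singer is assumed to vocalize.
#' @param arrival_jitter_sd Standard deviation (s) of Gaussian jitter added
#'   independently to each per-channel arrival time; emulates residual
#'   synchronization and propagation errors that perturb measured time
#'   differences of arrival.
#' @param quantize_12bit Quantize rendered waveforms to 12-bit resolution.
#' @param seed RNG seed controlling noise and jitter; fixed seed gives
#'   bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sound_speed = 1480, snr_db = Inf, ref_range = 5000,
                       ref_source_level = 165, spreading_exponent = 1,
                       band = c(10, 585), source_depth = 15,
                       arrival_jitter_sd = 0, quantize_12bit = FALSE,
                       seed = NULL) {
  stop_if_not_positive(sound_speed, "sound_speed")
  stop_if_not_positive(ref_range, "ref_range")
  structure(list(sound_speed = sound_speed, snr_db = snr_db,
                 ref_range = ref_range, ref_source_level = ref_source_level,
                 spreading_exponent = spreading_exponent, band = band,
                 source_depth = source_depth,
                 arrival_jitter_sd = arrival_jitter_sd,
                 quantize_12bit = quantize_12bit, seed = seed),
            class = "sim_config")
}

#' Schedule of emitted song units
#'
#' Describes when the simulated singer emits song units and what each unit
#' is: a constant tone or a linear frequency-modulated sweep within the
#' 10-585 Hz band of the recorders, with a source level in the measured
#' 151-173 dB re 1 uPa range.
#'
#' @param t_emit Emission times in seconds (track timeline).
#' @param kind `"sweep"` or `"tone"` (recycled).
#' @param f0,f1 Start/end frequency in Hz (for a tone, `f1` is ignored).
#' @param duration Unit duration in seconds.
#' @param source_level Source level in dB re 1 uPa at 1 m.
#' @return An `emission_schedule` data frame.
#' @export
emission_schedule <- function(t_emit, kind = "sweep", f0 = 100, f1 = 400,
                              duration = 1.5, source_level = 165) {
  n <- length(t_emit)
  sched <- data.frame(t_emit = t_emit,
                      kind = rep_len(kind, n), f0 = rep_len(f0, n),
                      f1 = rep_len(f1, n), duration = rep_len(duration, n),
                      source_level = rep_len(source_level, n))
  if (any(sched$f0 < 10 | sched$f0 > 585 | sched$f1 < 10 | sched$f1 > 585)) {
    stop("unit frequencies must lie within the 10-585 Hz band", call. = FALSE)
  }
  if (any(sched$duration <= 0)) stop("unit duration must be > 0", call. = FALSE)
  sched <- sched[order(sched$t_emit), , drop = FALSE]
  if (n > 1L && any(diff(sched$t_emit) < sched$duration[-n])) {
    stop("units must not overlap (inter-unit gaps must be >= 0)", call. = FALSE)
  }
  structure(sched, class = c("emission_schedule", "data.frame"))
}

#' @rdname emission_schedule
#' @param track A `source_track`; units are scheduled at regular intervals
#'   over its time span.
#' @param interval Inter-unit interval in seconds.
#' @param ... Passed to `emission_schedule()`.
#' @export
regular_schedule <- function(track, interval = 90, ...) {
  t0 <- min(track$t)
  t1 <- max(track$t)
  emission_schedule(seq(t0 + interval / 2, t1, by = interval), ...)
}

# One emitted unit sampled at offsets tau (s) from its onset, with a short
# cosine taper so units start and end without broadband clicks.
unit_waveform <- function(tau, kind, f0, f1, duration, taper_frac = 0.05) {
  phase <- if (kind == "tone") {
    2 * pi * f0 * tau
  } else {
    2 * pi * (f0 * tau + (f1 - f0) * tau^2 / (2 * duration))
  }
  w <- sin(phase)
  tp <- taper_frac * duration
  ramp_in <- pmin(tau / tp, 1)
  ramp_out <- pmin((duration - tau) / tp, 1)
  w * pmin(ramp_in, ramp_out, 1)
}

# dB re 1 uPa at 1 m -> relative pressure amplitude (165 dB == 1).
source_amplitude <- function(source_level) 10^((source_level - 165) / 20)

#' Render a multichannel array recording of a moving singer
#'
#' Synthesizes the waveform each hydrophone records: every scheduled unit is
#' emitted from the singer's position at its emission time, arrives on
#' channel i delayed by the slant range to sensor i divided by the sound
#' speed, is attenuated by `range^-spreading_exponent`, and is superimposed
#' on band-limited Gaussian ambient noise. Per-sensor clock drift from the
#' array's synchronization record is applied linearly over the deployment
#' span, so each channel's samples are on its own (drifting) recorder clock.
#' Arrivals are placed with fractional-sample accuracy by evaluating the unit
#' waveform on each channel's sample grid.
#'
#' @param array A [hydrophone_array()].
#' @param track A [simulate_track()] result (ground-truth singer path).
#' @param schedule An [emission_schedule()]; emission times must fall within
#'   the track's time span.
#' @param cfg A [sim_config()].
#' @param t_end Recording end time in seconds; defaults to just after the
#'   last arrival.
#' @return An `array_recording`: list with `wave` (samples x channels
#'   matrix), `fs`, `array`, and `truth`, a ground-truth log (one row per
#'   unit x channel) with emission position and true and recorded arrival
#'   times.
#' @export
render_recording <- function(array, track, schedule, cfg = sim_config(),
                             t_end = NULL) {
  fs <- array$sample_rate
  if (max(schedule$f0, schedule$f1) >= fs / 2) {
    stop("aliasing: unit frequencies must be below the Nyquist frequency",
         call. = FALSE)
  }
  if (min(schedule$t_emit) < min(track$t) ||
      max(schedule$t_emit + schedule$duration) > max(track$t)) {
    stop("emission times must fall within the track time span", call. = FALSE)
  }
  sens <- array$sensors
  ns <- nrow(sens)
  ne <- nrow(schedule)
  with_seed(cfg$seed, {
    ex <- stats::approx(track$t, track$x, xout = schedule$t_emit)$y
    ey <- stats::approx(track$t, track$y, xout = schedule$t_emit)$y
    truth <- vector("list", ne)
    arr_true <- matrix(0, ne, ns)
    for (e in seq_len(ne)) {
      r_h2 <- (ex[e] - sens$x)^2 + (ey[e] - sens$y)^2
      r_slant <- sqrt(r_h2 + (sens$depth - cfg$source_depth)^2)
      jit <- if (cfg$arrival_jitter_sd > 0) {
        stats::rnorm(ns, 0, cfg$arrival_jitter_sd)
      } else rep(0, ns)
      arr_true[e, ] <- schedule$t_emit[e] + r_slant / cfg$sound_speed + jit
    }
    # recorded (drifting-clock) arrival times per channel
    cs <- array$clock_sync
    arr_rec <- arr_true
    for (k in seq_len(ns)) {
      arr_rec[, k] <- arr_true[, k] +
        drift_offset(arr_true[, k], cs$offset_start[k], cs$offset_end[k],
                     cs$span[k])
    }
    if (is.null(t_end)) t_end <- max(arr_rec + schedule$duration) + 0.5
    nsamp <- ceiling(t_end * fs)
    wave <- matrix(0, nsamp, ns)
    for (e in seq_len(ne)) {
      r_h <- sqrt((ex[e] - sens$x)^2 + (ey[e] - sens$y)^2)
      r_slant <- sqrt(r_h^2 + (sens$depth - cfg$source_depth)^2)
      amp <- source_amplitude(schedule$source_level[e]) /
        r_slant^cfg$spreading_exponent
      for (k in seq_len(ns)) {
        a <- arr_rec[e, k]
        i0 <- max(1L, ceiling(a * fs) + 1L)
        i1 <- min(nsamp, floor((a + schedule$duration[e]) * fs) + 1L)
        if (i1 < i0) next
        tau <- (seq(i0, i1) - 1) / fs - a
        wave[i0:i1, k] <- wave[i0:i1, k] +
          amp[k] * unit_waveform(tau, schedule$kind[e], schedule$f0[e],
                                 schedule$f1[e], schedule$duration[e])
      }
    }
    if (is.finite(cfg$snr_db)) {
      noise_rms <- source_amplitude(cfg$ref_source_level) /
        cfg$ref_range^cfg$spreading_exponent / 10^(cfg$snr_db / 20)
      bf <- signal::butter(4, cfg$band / (fs / 2), type = "pass")
      for (k in seq_len(ns)) {
        wave[, k] <- wave[, k] +
          signal::filtfilt(bf, stats::rnorm(nsamp, 0, noise_rms))
      }
    }
    if (isTRUE(cfg$quantize_12bit)) {
      peak <- max(abs(wave), 1e-12)
      wave <- round(wave / peak * 2047) / 2047 * peak
    }
    truth <- data.frame(
      unit = rep(seq_len(ne), each = ns),
      t_emit = rep(schedule$t_emit, each = ns),
      x = rep(ex, each = ns), y = rep(ey, each = ns),
      channel = rep(sens$id, ne),
      arrival_true = as.vector(t(arr_true)),
      arrival_recorded = as.vector(t(arr_rec)))
    structure(list(wave = wave, fs = fs, array = array, truth = truth,
                   schedule = schedule, cfg = cfg),
              class = "array_recording")
  })
}

#' @export
print.array_recording <- function(x, ...) {
  cat(sprintf("Array recording: %d channels x %.1f s at %g Hz (%d units)\n",
              ncol(x$wave), nrow(x$wave) / x$fs, x$fs,
              length(unique(x$truth$unit))))
  invisible(x)
}

#' Build a selection table from a recording's ground-truth log
#'
#' Mirrors an analyst marking each song unit on the spectrogram: the
#' selection brackets the unit's arrivals across all channels, padded on
#' both sides.
#'
#' @param recording An `array_recording`.
#' @param pad Padding in seconds on each side of the arrival span.
#' @param session Session identifier attached to every selection.
#' @return A `selection_table` data frame (Raven-style columns).
#' @export
selections_from_truth <- function(recording, pad = 0.5, session = "S1") {
  tr <- recording$truth
  sp <- split(tr, tr$unit)
  rows <- lapply(sp, function(u) {
    data.frame(Selection = u$unit[1],
               `Begin Time (s)` = min(u$arrival_recorded) - pad,
               `End Time (s)` = max(u$arrival_recorded) +
                 recording$schedule$duration[u$unit[1]] + pad,
               `Low Freq (Hz)` = min(recording$schedule$f0[u$unit[1]],
                                     recording$schedule$f1[u$unit[1]]),
               `High Freq (Hz)` = max(recording$schedule$f0[u$unit[1]],
                                      recording$schedule$f1[u$unit[1]]),
               Channel = NA, Session = session, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out$Channel <- paste(recording$array$sensors$id, collapse = ";")
  rownames(out) <- NULL
  structure(out, class = c("selection_table", "data.frame"))
}

#' Simulate calibration playbacks at known positions
#'
#' Plays frequency-modulated sweep tones from known locations and depths
#' within the array — the field procedure used to measure localization error
#' when the localizer itself reports none — and logs each sweep with its true
#' position.
#'
#' @param array A [hydrophone_array()].
#' @param positions Data frame with columns `x`, `y` and optionally `depth`
#'   (m) of the playback stations; must be non-empty.
#' @param n_per_position Number of sweeps played at each station; a scalar
#'   or one count per station.
#' @param cfg A [sim_config()].
#' @param interval Seconds between consecutive sweeps at a station; keep
#'   larger than twice the maximum array time-difference-of-arrival so
#'   neighbouring sweeps never enter the same correlation window.
#' @param ... Unit parameters passed to [emission_schedule()].
#' @return A `calibration_playbacks` object: list of one `array_recording`
#'   per station plus a `log` data frame (sweep, position, x, y, depth,
#'   t_emit).
#' @export
simulate_calibration_playbacks <- function(array, positions, n_per_position,
                                           cfg = sim_config(), interval = 40,
                                           ...) {
  if (NROW(positions) == 0L) {
    stop("`positions` must contain at least one playback station",
         call. = FALSE)
  }
  if (any(n_per_position <= 0)) {
    stop("`n_per_position` must be positive", call. = FALSE)
  }
  n_per_position <- rep_len(n_per_position, nrow(positions))
  if (is.null(positions$depth)) positions$depth <- cfg$source_depth
  recs <- vector("list", nrow(positions))
  logs <- vector("list", nrow(positions))
  base_seed <- if (is.null(cfg$seed)) NULL else cfg$seed
  for (p in seq_len(nrow(positions))) {
    cfg_p <- cfg
    cfg_p$seed <- if (is.null(base_seed)) NULL else base_seed + p
    cfg_p$source_depth <- positions$depth[p]
    t_emit <- seq(interval, by = interval, length.out = n_per_position[p])
    span <- max(t_emit) + interval
    station <- structure(
      data.frame(t = c(0, span), x = rep(positions$x[p], 2),
                 y = rep(positions$y[p], 2)),
      class = c("source_track", "data.frame"))
    sched <- emission_schedule(t_emit, kind = "sweep", ...)
    recs[[p]] <- render_recording(array, station, sched, cfg_p)
    logs[[p]] <- data.frame(position = p, sweep = seq_len(n_per_position[p]),
                            x = positions$x[p], y = positions$y[p],
                            depth = positions$depth[p], t_emit = t_emit)
  }
  structure(list(recordings = recs, log = do.call(rbind, logs),
                 array = array, cfg = cfg),
            class = "calibration_playbacks")
}

#' @export
print.calibration_playbacks <- function(x, ...) {
  cat(sprintf("Calibration playbacks: %d sweeps at %d positions\n",
              nrow(x$log), length(unique(x$log$position))))
  invisible(x)
}
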