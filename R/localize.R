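#' Predicted pairwise time differences of arrival
#'
#' For a candidate horizontal position, the predicted delay between channels
#' i and j is `(range_i - range_j) / sound_speed`, using horizontal ranges
#' only (the localizer works in the horizontal plane; any slant-range bias
#' is absorbed into measured calibration error, as in a field calibration).
#'
#' @param candidate Numeric `c(x, y)` position in meters.
#' @param array A [hydrophone_array()].
#' @param sound_speed Sound speed in m/s.
#' @return An antisymmetric matrix of delays in seconds, `[i, j]` = arrival
#'   at i minus arrival at j.
#' @examples
#' arr <- hydrophone_array(c(0, 1000, 0), c(0, 0, 1000), c(50, 50, 50))
#' predicted_tdoa(c(500, 500), arr, 1480)
#' @export
predicted_tdoa <- function(candidate, array, sound_speed = 1480) {
  stopifnot(length(candidate) == 2L, all(is.finite(candidate)))
  stop_if_not_positive(sound_speed, "sound_speed")
  r <- horizontal_ranges(matrix(candidate, 1), array)[1, ]
  d <- outer(r, r, "-") / sound_speed
  dimnames(d) <- list(array$sensors$id, array$sensors$id)
  d
}

# --- internal clip and cross-correlation machinery ------------------------

# Extract per-channel clips covering [begin - margin, end + margin] on the
# *true* timeline, undoing each sensor's clock drift by shifting the read
# position; tau[k] is the exact true time of clip k's first sample, so
# sub-sample drift residuals are carried into the predicted lags.
extract_clips <- function(recording, begin, end, channels, margin) {
  fs <- recording$fs
  sens <- recording$array$sensors
  cs <- recording$array$clock_sync
  cols <- match(channels, sens$id)
  if (anyNA(cols)) {
    stop("selection channels not present in recording", call. = FALSE)
  }
  T0 <- begin - margin
  len <- round((end - begin + 2 * margin) * fs)
  nsamp <- nrow(recording$wave)
  x <- vector("list", length(cols))
  tau <- numeric(length(cols))
  for (k in seq_along(cols)) {
    j <- cols[k]
    off <- drift_offset((begin + end) / 2, cs$offset_start[j],
                        cs$offset_end[j], cs$span[j])
    i0 <- round((T0 + off) * fs) + 1L
    idx <- seq(i0, i0 + len - 1L)
    keep <- idx >= 1L & idx <= nsamp
    v <- numeric(len)
    v[keep] <- recording$wave[idx[keep], j]
    x[[k]] <- v
    tau[k] <- (i0 - 1L) / fs - off
  }
  list(x = x, tau = tau, fs = fs, channels = channels, cols = cols)
}

# Normalized pairwise cross-correlations up to +/- maxlag seconds, via FFT.
# ccf[, p] holds lags -K..K for pair p; value at lag l (samples) is
# sum x_i[n + l] x_j[n] / (||x_i|| ||x_j||) after mean removal.
pair_ccfs <- function(clips, maxlag) {
  fs <- clips$fs
  m <- length(clips$x)
  if (m < 3L) stop("need at least 3 channels", call. = FALSE)
  K <- ceiling(maxlag * fs)
  L <- max(lengths(clips$x))
  nfft <- stats::nextn(L + K + 1L, 2)
  FX <- vector("list", m)
  norms <- numeric(m)
  for (k in seq_len(m)) {
    xc <- clips$x[[k]] - mean(clips$x[[k]])
    norms[k] <- sqrt(sum(xc^2))
    FX[[k]] <- stats::fft(c(xc, numeric(nfft - length(xc))))
  }
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  np <- nrow(pairs)
  idx <- c(seq(nfft - K + 1L, nfft), seq_len(K + 1L))   # lags -K..K
  ccf <- matrix(0, 2L * K + 1L, np)
  short <- logical(np)
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (norms[i] <= 0 || norms[j] <= 0) { short[p] <- TRUE; next }
    cc <- Re(stats::fft(FX[[i]] * Conj(FX[[j]]), inverse = TRUE)) / nfft
    ccf[, p] <- cc[idx] / (norms[i] * norms[j])
  }
  list(ccf = ccf, pairs = pairs, K = K, fs = fs, tau = clips$tau,
       channels = clips$channels, degenerate = short,
       env_cache = new.env(parent = emptyenv()))
}

# Exact sliding maximum of x over a centered window of half-width w samples,
# by logarithmic doubling of forward-window maxima.
sliding_max <- function(x, w) {
  if (w <= 0L) return(x)
  n <- length(x)
  len <- 2L * w + 1L
  lead <- function(y, s) c(y[(s + 1L):n], rep(-Inf, s))
  y <- x
  k <- 1L
  while (k < len) {
    s <- min(k, len - k)
    y <- pmax(y, lead(y, s))
    k <- k + s
  }
  # y[i] = max over [i, i + 2w]; recenter to [i - w, i + w]
  c(rep(-Inf, w), y)[seq_len(n)]
}

# Envelope of pair p's cross-correlation, max-filtered over +/- smooth
# seconds; cached per smoothing width. At coarse grid resolutions the raw
# correlation mainlobe (width ~ 1/signal bandwidth, a few meters in space)
# falls between grid nodes, so each level scores a candidate by the best
# correlation within the lag window its cell subtends.
ccf_envelope <- function(ccfs, p, smooth) {
  w <- as.integer(round(smooth * ccfs$fs))
  key <- sprintf("w%d_p%d", w, p)
  env <- ccfs$env_cache
  if (!is.null(env[[key]])) return(env[[key]])
  e <- sliding_max(abs(ccfs$ccf[, p]), w)
  env[[key]] <- e
  e
}

# Catmull-Rom cubic interpolation of pair p's ccf at fractional lag
# positions (seconds); NA outside the tabulated range.
ccf_interp <- function(ccfs, p, lag_s) {
  pos <- lag_s * ccfs$fs + ccfs$K + 1
  n <- nrow(ccfs$ccf)
  i <- floor(pos)
  u <- pos - i
  ok <- !is.na(i) & i >= 2 & (i + 2) <= n
  out <- rep(NA_real_, length(pos))
  if (!any(ok)) return(out)
  ii <- i[ok]; uu <- u[ok]
  cc <- ccfs$ccf[, p]
  p0 <- cc[ii - 1]; p1 <- cc[ii]; p2 <- cc[ii + 1]; p3 <- cc[ii + 2]
  out[ok] <- 0.5 * (2 * p1 + (p2 - p0) * uu +
                      (2 * p0 - 5 * p1 + 4 * p2 - p3) * uu^2 +
                      (3 * p1 - p0 - 3 * p2 + p3) * uu^3)
  out
}

# Correlation sum over candidate positions (n x 2 matrix). For each channel
# pair the normalized cross-correlation is read off at the lag the candidate
# predicts; with `smooth > 0` (coarse grid levels) the max-filtered envelope
# over +/- smooth seconds is used instead, so a cell scores high whenever
# the true lag falls anywhere within it. Pairs whose predicted lag falls
# outside the tabulated range are skipped and counted; candidates with
# fewer than `min_pairs` usable pairs score NA.
correlation_sum_grid <- function(cand, ccfs, array, sound_speed,
                                 min_pairs = 3, smooth = 0) {
  sens_idx <- match(ccfs$channels, array$sensors$id)
  sub <- array
  sub$sensors <- array$sensors[sens_idx, , drop = FALSE]
  R <- horizontal_ranges(cand, sub)
  np <- nrow(ccfs$pairs)
  n <- nrow(ccfs$ccf)
  score <- numeric(nrow(cand))
  used <- integer(nrow(cand))
  for (p in seq_len(np)) {
    if (ccfs$degenerate[p]) next
    i <- ccfs$pairs[p, 1]; j <- ccfs$pairs[p, 2]
    lag <- (R[, i] - R[, j]) / sound_speed - (ccfs$tau[i] - ccfs$tau[j])
    if (smooth > 0) {
      e <- ccf_envelope(ccfs, p, smooth)
      pos <- round(lag * ccfs$fs) + ccfs$K + 1
      ok <- pos >= 1 & pos <= n
      v <- rep(NA_real_, length(pos))
      v[ok] <- e[pos[ok]]
    } else {
      v <- ccf_interp(ccfs, p, lag)
    }
    ok <- !is.na(v) & is.finite(v)
    score[ok] <- score[ok] + v[ok]
    used <- used + ok
  }
  score[used < min_pairs] <- NA_real_
  list(score = score, n_used = used, n_pairs = np)
}

#' Correlation sum of a candidate source position
#'
#' The objective function of correlation-sum localization: for each channel
#' pair, the normalized waveform cross-correlation of the two clips is
#' evaluated at the time lag predicted by the candidate position, and the
#' values are summed over all pairs. A noise-free unit scores the number of
#' pairs at its true position (every pair aligns perfectly); unrelated noise
#' scores near zero. The score is invariant under a common time shift of all
#' channels, since only pairwise lag differences enter.
#'
#' @param candidate `c(x, y)` in meters, or an n x 2 matrix of candidates.
#' @param recording An `array_recording` (or any list with `wave`, `fs`,
#'   `array`).
#' @param begin,end Time bounds (s) of the selected unit.
#' @param channels Sensor ids to use (>= 3).
#' @param sound_speed Sound speed in m/s.
#' @param margin Clip margin in seconds; defaults to the maximum possible
#'   time difference of arrival across the array plus 0.1 s.
#' @return Numeric score(s); attribute `n_used` gives usable pairs per
#'   candidate.
#' @export
correlation_sum <- function(candidate, recording, begin, end,
                            channels = recording$array$sensors$id,
                            sound_speed = 1480, margin = NULL) {
  if (is.null(margin)) margin <- default_margin(recording$array, sound_speed)
  clips <- extract_clips(recording, begin, end, channels, margin)
  ccfs <- pair_ccfs(clips, maxlag = margin)
  cand <- if (is.matrix(candidate)) candidate else matrix(candidate, 1)
  res <- correlation_sum_grid(cand, ccfs, recording$array, sound_speed)
  structure(res$score, n_used = res$n_used)
}

#' Pairwise cross-correlations for one selected unit
#'
#' Extracts the per-channel clips for a selection (with the clip margin
#' needed to cover any possible array time difference of arrival) and
#' computes all pairwise normalized cross-correlations. The result can be
#' passed to [cse_localize()] via its `ccfs` argument to localize the same
#' unit repeatedly (e.g. iterative vs exhaustive search) without repeating
#' the FFT work.
#'
#' @param selection One selection (see [cse_localize()]).
#' @param recording An `array_recording`.
#' @param sound_speed Sound speed in m/s.
#' @return An opaque pairwise cross-correlation object.
#' @export
unit_ccfs <- function(selection, recording, sound_speed = 1480) {
  sel <- if (is.data.frame(selection)) selection_record(selection)
         else selection
  margin <- default_margin(recording$array, sound_speed)
  clips <- extract_clips(recording, sel$begin, sel$end, sel$channels, margin)
  pair_ccfs(clips, maxlag = margin)
}

default_margin <- function(array, sound_speed) {
  d <- stats::dist(cbind(array$sensors$x, array$sensors$y))
  max(d) / sound_speed + 0.1
}

#' Search grid for correlation-sum localization
#'
#' The candidate grid: the array bounding box plus a margin, scanned at a
#' coarse resolution, then iteratively re-gridded around the running argmax
#' at `refine_factor` finer resolution for `refine_levels` levels (defaults:
#' 200 m coarse, two levels of 10x refinement, final 2 m).
#'
#' @param array A [hydrophone_array()].
#' @param margin Margin in meters beyond the array bounding box.
#' @param resolution Coarse cell size in meters.
#' @param refine_factor Resolution gain per refinement level.
#' @param refine_levels Number of refinement levels.
#' @param xlim,ylim Optional explicit extents (override bbox + margin).
#' @return A `search_grid` list.
#' @export
search_grid <- function(array, margin = 5000, resolution = 200,
                        refine_factor = 10, refine_levels = 2,
                        xlim = NULL, ylim = NULL) {
  stop_if_not_positive(resolution, "resolution")
  s <- array$sensors
  if (is.null(xlim)) xlim <- range(s$x) + c(-margin, margin)
  if (is.null(ylim)) ylim <- range(s$y) + c(-margin, margin)
  structure(list(xlim = xlim, ylim = ylim, resolution = resolution,
                 refine_factor = refine_factor,
                 refine_levels = refine_levels),
            class = "search_grid")
}

grid_candidates <- function(xlim, ylim, res) {
  xs <- seq(xlim[1], xlim[2], by = res)
  ys <- seq(ylim[1], ylim[2], by = res)
  list(xs = xs, ys = ys,
       cand = cbind(rep(xs, times = length(ys)),
                    rep(ys, each = length(xs))))
}

#' Localize a selected song unit by correlation-sum grid search
#'
#' Evaluates the correlation sum on a coarse horizontal grid, then refines
#' around the argmax for the configured number of levels; the final-level
#' argmax is the location estimate ("the point that maximizes the sum").
#' Ties are broken by scan order (x fastest, then y). An argmax on the grid
#' boundary triggers a warning (the source likely lies outside the search
#' area). Quality control compares the measured pairwise peak lags with the
#' lags the estimate predicts; estimates whose worst residual exceeds
#' `qc_tolerance` are flagged `fail` and excluded from track building.
#'
#' @param selection One selection: a one-row `selection_table` data frame or
#'   the list returned by [selection_record()].
#' @param recording An `array_recording` (simulated or read from WAV).
#' @param grid A [search_grid()]; defaults to one built from the array.
#' @param sound_speed Sound speed in m/s.
#' @param qc_tolerance Lag-agreement tolerance in seconds (default 10 ms,
#'   i.e. 20 samples at 2 kHz).
#' @param min_pairs Minimum usable channel pairs; fewer rejects the estimate.
#' @param method `"iterative"` (default) or `"exhaustive"`: the latter
#'   replaces the intermediate refinement levels with a single exhaustive
#'   scan at the final resolution around the coarse argmax, and exists as a
#'   slow reference for validating the iterative schedule.
#' @param ccfs Precomputed pairwise cross-correlation object from a previous
#'   call on the same selection (expert use: avoids re-extracting clips when
#'   localizing the same unit with several methods or grids).
#' @return A `location_estimate`: list with the unit's midpoint time `t`,
#'   `x`, `y`, `score`, `qc` (`"pass"`/`"fail"`), `qc_residual` (worst lag
#'   residual, s), `n_channels`, `n_pairs_used`, and bookkeeping fields.
#' @export
cse_localize <- function(selection, recording, grid = NULL,
                         sound_speed = 1480, qc_tolerance = 0.010,
                         min_pairs = 3,
                         method = c("iterative", "exhaustive"),
                         ccfs = NULL) {
  method <- match.arg(method)
  array <- recording$array
  if (is.null(grid)) grid <- search_grid(array)
  sel <- if (is.data.frame(selection)) selection_record(selection)
         else selection
  if (is.null(ccfs)) {
    margin <- default_margin(array, sound_speed)
    clips <- extract_clips(recording, sel$begin, sel$end, sel$channels,
                           margin)
    ccfs <- pair_ccfs(clips, maxlag = margin)
  }
  if (sum(!ccfs$degenerate) < min_pairs) {
    stop("all channel pairs unusable; no estimate possible", call. = FALSE)
  }
  g <- grid_candidates(grid$xlim, grid$ylim, grid$resolution)
  res <- correlation_sum_grid(g$cand, ccfs, array, sound_speed, min_pairs,
                              smooth = 1.5 * grid$resolution / sound_speed)
  if (all(is.na(res$score))) {
    stop("no candidate had enough usable channel pairs", call. = FALSE)
  }
  best <- which.max(res$score)          # first-in-scan-order tie break
  bx <- g$cand[best, 1]; by <- g$cand[best, 2]
  nx <- length(g$xs); ny <- length(g$ys)
  on_boundary <- (best - 1) %% nx %in% c(0, nx - 1) ||
    (best - 1) %/% nx %in% c(0, ny - 1)
  if (on_boundary) {
    warning("correlation-sum argmax on grid boundary; ",
            "source may lie outside the search area", call. = FALSE)
  }
  final_res <- grid$resolution / grid$refine_factor^grid$refine_levels
  if (method == "iterative") {
    prev_res <- grid$resolution
    for (lvl in seq_len(grid$refine_levels)) {
      res_l <- grid$resolution / grid$refine_factor^lvl
      w <- 2 * prev_res
      sm <- if (lvl < grid$refine_levels) 1.5 * res_l / sound_speed else 0
      gl <- grid_candidates(c(bx - w, bx + w), c(by - w, by + w), res_l)
      rl <- correlation_sum_grid(gl$cand, ccfs, array, sound_speed,
                                 min_pairs, smooth = sm)
      if (!all(is.na(rl$score))) {
        b <- which.max(rl$score)
        bx <- gl$cand[b, 1]; by <- gl$cand[b, 2]
      }
      prev_res <- res_l
    }
  } else {
    w <- 2 * grid$resolution
    gl <- grid_candidates(c(bx - w, bx + w), c(by - w, by + w), final_res)
    rl <- correlation_sum_grid(gl$cand, ccfs, array, sound_speed, min_pairs)
    if (!all(is.na(rl$score))) {
      b <- which.max(rl$score)
      bx <- gl$cand[b, 1]; by <- gl$cand[b, 2]
    }
  }
  fin <- correlation_sum_grid(matrix(c(bx, by), 1), ccfs, array, sound_speed,
                              min_pairs)
  meas <- measured_peak_lags(ccfs)
  qc <- qc_location(c(bx, by), meas, array, sound_speed,
                    tolerance = qc_tolerance)
  structure(list(session = sel$session, unit = sel$id,
                 t = (sel$begin + sel$end) / 2, x = bx, y = by,
                 score = fin$score[1], n_channels = length(sel$channels),
                 n_pairs_used = fin$n_used[1],
                 n_pairs_skipped = fin$n_pairs - fin$n_used[1],
                 qc = if (qc$pass) "pass" else "fail",
                 qc_residual = qc$max_residual,
                 on_boundary = on_boundary, method = method),
            class = "location_estimate")
}

#' @export
print.location_estimate <- function(x, ...) {
  cat(sprintf(
    "Location estimate (unit %s, t = %.1f s): x = %.1f m, y = %.1f m\n",
    x$unit, x$t, x$x, x$y))
  cat(sprintf("  correlation sum %.3f over %d/%d pairs; QC %s (residual %.2f ms)\n",
              x$score, x$n_pairs_used, x$n_pairs_used + x$n_pairs_skipped,
              x$qc, 1000 * x$qc_residual))
  invisible(x)
}

#' Measured pairwise peak lags
#'
#' Argmax of each pair's cross-correlation with parabolic sub-sample
#' refinement, reported on the true timeline (clip-start offsets removed) so
#' the values compare directly with [predicted_tdoa()].
#'
#' @param ccfs Internal pairwise cross-correlation object (as produced
#'   inside [cse_localize()] / [correlation_sum()]).
#' @return Data frame with channel ids `i`, `j` and `lag` (s).
#' @keywords internal
measured_peak_lags <- function(ccfs) {
  np <- nrow(ccfs$pairs)
  lag <- rep(NA_real_, np)
  n <- nrow(ccfs$ccf)
  for (p in seq_len(np)) {
    if (ccfs$degenerate[p]) next
    cc <- ccfs$ccf[, p]
    k <- which.max(cc)
    delta <- 0
    if (k > 1 && k < n) {
      denom <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
      if (denom < 0) delta <- 0.5 * (cc[k - 1] - cc[k + 1]) / denom
    }
    # local peak lag, then back onto the true timeline via the clip starts
    lag[p] <- (k + delta - ccfs$K - 1) / ccfs$fs +
      (ccfs$tau[ccfs$pairs[p, 1]] - ccfs$tau[ccfs$pairs[p, 2]])
  }
  data.frame(i = ccfs$channels[ccfs$pairs[, 1]],
             j = ccfs$channels[ccfs$pairs[, 2]],
             lag = lag)
}

#' Quality-control a location estimate against measured lags
#'
#' An estimate passes if, for every usable channel pair, the lag it predicts
#' agrees with the measured cross-correlation peak lag within `tolerance`
#' seconds. This is the numeric analogue of the analyst's check that "the
#' estimated location agrees with the observed arrival-time differences";
#' failing estimates are excluded from tracks.
#'
#' @param estimate `c(x, y)` in meters.
#' @param measured Data frame with columns `i`, `j` (sensor ids) and `lag`
#'   (s) on the true timeline, e.g. from [measured_peak_lags()].
#' @param array A [hydrophone_array()].
#' @param sound_speed Sound speed in m/s.
#' @param tolerance Maximum acceptable |predicted - measured| lag, seconds.
#' @return List with `pass` (logical), `max_residual` (s) and per-pair
#'   `residuals`.
#' @export
qc_location <- function(estimate, measured, array, sound_speed = 1480,
                        tolerance = 0.010) {
  td <- predicted_tdoa(estimate, array, sound_speed)
  ids <- array$sensors$id
  pred <- td[cbind(match(measured$i, ids), match(measured$j, ids))]
  resid <- abs(pred - measured$lag)
  ok <- !is.na(resid)
  list(pass = all(resid[ok] <= tolerance),
       max_residual = if (any(ok)) max(resid[ok]) else NA_real_,
       residuals = resid)
}

#' Localize every selection in a table
#'
#' @param selections A `selection_table`.
#' @param recording An `array_recording`.
#' @param ... Passed to [cse_localize()].
#' @return A `location_set` data frame: one row per selection with columns
#'   `session`, `unit`, `t`, `x`, `y`, `score`, `qc`, `n_channels`.
#' @export
localize_selections <- function(selections, recording, ...) {
  rows <- lapply(seq_len(nrow(selections)), function(r) {
    est <- cse_localize(selections[r, , drop = FALSE], recording, ...)
    data.frame(session = est$session, unit = est$unit, t = est$t,
               x = est$x, y = est$y, score = est$score, qc = est$qc,
               qc_residual = est$qc_residual, n_channels = est$n_channels)
  })
  structure(do.call(rbind, rows),
            class = c("location_set", "data.frame"))
}

#' @export
summary.location_set <- function(object, ...) {
  cat(sprintf("Location set: %d estimates, %d QC-passed (%.0f%%)\n",
              nrow(object), sum(object$qc == "pass"),
              100 * mean(object$qc == "pass")))
  invisible(object)
}

#' Localization error against known source positions
#'
#' Per-sweep error is the horizontal Euclidean distance between the
#' acoustically estimated and the known source location; the result reports
#' the per-sweep errors with their mean and standard deviation, the field
#' measure of localization accuracy.
#'
#' @param estimates Data frame (or `location_set`) with columns `x`, `y`,
#'   one row per sweep.
#' @param known Data frame with columns `x`, `y`: the true position of each
#'   sweep (same row order), plus optionally `position` (station id).
#' @return A `calibration_result`: list with `errors` (m), `mean_error`,
#'   `sd_error`, `n_sweeps`, `n_positions`.
#' @examples
#' est <- data.frame(x = 30, y = 40)
#' calibration_error(est, data.frame(x = 0, y = 0))$mean_error  # 50 m
#' @export
calibration_error <- function(estimates, known) {
  if (NROW(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
  if (NROW(estimates) != NROW(known)) {
    stop("need one known position per estimate", call. = FALSE)
  }
  err <- sqrt((estimates$x - known$x)^2 + (estimates$y - known$y)^2)
  npos <- if (!is.null(known$position)) length(unique(known$position))
          else nrow(unique(known[, c("x", "y")]))
  structure(list(errors = err, mean_error = mean(err),
                 sd_error = stats::sd(err), n_sweeps = length(err),
                 n_positions = npos),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration: mean localization error %.1f m (SD %.2f), %d sweeps at %d positions\n",
    x$mean_error, x$sd_error, x$n_sweeps, x$n_positions))
  invisible(x)
}

#' Run the calibration experiment end to end
#'
#' Localizes every sweep in a set of simulated calibration playbacks and
#' compares the estimates with the known playback positions.
#'
#' @param playbacks A [simulate_calibration_playbacks()] result.
#' @param grid A [search_grid()]; defaults to one built from the array.
#' @param ... Passed to [cse_localize()].
#' @return A list with `result` (a `calibration_result`) and `locations`
#'   (per-sweep estimates joined to truth).
#' @export
calibrate <- function(playbacks, grid = NULL, ...) {
  array <- playbacks$array
  if (is.null(grid)) grid <- search_grid(array)
  locs <- vector("list", length(playbacks$recordings))
  for (p in seq_along(playbacks$recordings)) {
    rec <- playbacks$recordings[[p]]
    sel <- selections_from_truth(rec, session = sprintf("CAL%d", p))
    ls <- localize_selections(sel, rec, grid = grid, ...)
    ls$position <- p
    locs[[p]] <- ls
  }
  locs <- do.call(rbind, locs)
  res <- calibration_error(locs, playbacks$log)
  list(result = res, locations = cbind(locs,
       known_x = playbacks$log$x, known_y = playbacks$log$y))
}
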