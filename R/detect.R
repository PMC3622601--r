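#' Spectrogram parameters for the template detector
#'
#' @param window Analysis window length in samples.
#' @param overlap Window overlap as a fraction in `[0, 1)`.
#' @param fft FFT size in samples (>= `window`).
#' @param band Frequency band in Hz used for correlation; must be below the
#'   Nyquist frequency.
#' @return A `spectrogram_params` list.
#' @export
spectrogram_params <- function(window = 256, overlap = 0.75, fft = 256,
                               band = c(10, 585)) {
  if (overlap < 0 || overlap >= 1) {
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  }
  stopifnot(fft >= window, length(band) == 2L, band[1] < band[2])
  structure(list(window = window, overlap = overlap, fft = fft, band = band),
            class = "spectrogram_params")
}

# Band-restricted magnitude spectrogram (freq x frames) of one channel.
band_spectrogram <- function(x, fs, params) {
  if (max(params$band) >= fs / 2) {
    stop("spectrogram band must be below the Nyquist frequency",
         call. = FALSE)
  }
  sp <- signal::specgram(x, n = params$fft, Fs = fs,
                         window = signal::hanning(params$window),
                         overlap = round(params$window * params$overlap))
  keep <- sp$f >= params$band[1] & sp$f <= params$band[2]
  list(S = Mod(sp$S[keep, , drop = FALSE]), t = sp$t, f = sp$f[keep],
       hop = params$window - round(params$window * params$overlap))
}

#' Build a spectrogram template from a synthetic song unit
#'
#' Renders one unit (default: the simulator's frequency-modulated sweep) at
#' the recorder sampling rate and reduces it to a band-restricted magnitude
#' spectrogram for use with [detect_template()].
#'
#' @param fs Sampling rate in Hz.
#' @param kind,f0,f1,duration Unit parameters (see [emission_schedule()]).
#' @param params [spectrogram_params()].
#' @return A `song_template`: list with the spectrogram matrix `S`, the
#'   waveform, `duration` and `params`.
#' @export
song_template <- function(fs = 2000, kind = "sweep", f0 = 100, f1 = 400,
                          duration = 1.5, params = spectrogram_params()) {
  tau <- seq(0, duration - 1 / fs, by = 1 / fs)
  w <- unit_waveform(tau, kind, f0, f1, duration)
  sp <- band_spectrogram(w, fs, params)
  structure(list(S = sp$S, waveform = w, duration = duration, fs = fs,
                 params = params),
            class = "song_template")
}

#' Detect song by normalized spectrogram cross-correlation
#'
#' Slides the template's magnitude spectrogram along the waveform's and
#' computes the normalized (Pearson) 2-D correlation at every frame offset:
#' both the template and each same-sized spectrogram window are centered and
#' scaled, so scores lie in `[-1, 1]` and an exact, frame-aligned copy of
#' the template scores 1. Local score maxima at or above `threshold`
#' (separated by at least half the template duration) become detection
#' events, sorted by time.
#'
#' @param wave Numeric vector or samples-x-channels matrix.
#' @param template A [song_template()] (or any list with an `S` spectrogram
#'   matrix and `duration`).
#' @param fs Sampling rate in Hz.
#' @param params [spectrogram_params()]; must match the template's.
#' @param threshold Minimum normalized correlation score.
#' @return A `detection_events` data frame: `channel`, `time` (s, center of
#'   the matched window) and `score`.
#' @export
detect_template <- function(wave, template, fs = 2000,
                            params = template$params, threshold = 0.5) {
  if (is.null(dim(wave))) wave <- matrix(wave, ncol = 1)
  if (NROW(template$S) == 0L || NCOL(template$S) == 0L) {
    stop("empty template", call. = FALSE)
  }
  events <- list()
  for (ch in seq_len(ncol(wave))) {
    x <- wave[, ch]
    if (length(x) <= length(template$waveform)) {
      stop("template must be shorter than the waveform", call. = FALSE)
    }
    sp <- band_spectrogram(x, fs, params)
    sc <- xcorr2_normalized(sp$S, template$S)
    if (!length(sc)) next
    min_sep <- max(1L, floor(template$duration / 2 * fs / sp$hop))
    pk <- local_maxima(sc, threshold, min_sep)
    if (!length(pk)) next
    frame_dt <- sp$hop / fs
    events[[length(events) + 1L]] <- data.frame(
      channel = ch,
      time = sp$t[1] + (pk - 1) * frame_dt + template$duration / 2,
      score = sc[pk])
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(channel = integer(), time = numeric(), score = numeric())
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("detection_events", "data.frame"))
}

# Normalized 2-D cross-correlation of template T against spectrogram S at
# every full-overlap frame offset. Windows with (near-)zero variance score 0.
xcorr2_normalized <- function(S, T) {
  r <- nrow(S); N <- ncol(S); m <- ncol(T)
  if (nrow(T) != r) stop("template/spectrogram band mismatch", call. = FALSE)
  K <- N - m + 1L
  if (K < 1L) return(numeric(0))
  Tc <- T - mean(T)
  tnorm <- sqrt(sum(Tc^2))
  num <- numeric(N)
  for (i in seq_len(r)) {
    num <- num + as.numeric(stats::filter(S[i, ], rev(Tc[i, ]), sides = 1))
  }
  num <- num[m:N]                       # windows starting at 1..K
  cs1 <- cumsum(c(0, colSums(S)))
  cs2 <- cumsum(c(0, colSums(S^2)))
  w1 <- cs1[(m + 1):(N + 1)] - cs1[1:K]
  w2 <- cs2[(m + 1):(N + 1)] - cs2[1:K]
  var_w <- pmax(w2 - w1^2 / (r * m), 0)
  denom <- sqrt(var_w) * tnorm
  score <- ifelse(denom > 1e-12 * r * m, num / denom, 0)
  pmin(pmax(score, -1), 1)
}

local_maxima <- function(x, threshold, min_sep) {
  n <- length(x)
  if (n < 1L) return(integer(0))
  cand <- which(x >= threshold &
                  x >= c(-Inf, x[-n]) & x >= c(x[-1], -Inf))
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (k in cand) {
    if (!length(keep) || all(abs(keep - k) >= min_sep)) keep <- c(keep, k)
  }
  sort(keep)
}

#' Aggregate detections to hourly and daily song presence
#'
#' An hour is song-present if it contains at least one (confirmed)
#' detection; the daily series counts present hours per day, the standard
#' summary of seasonal song occurrence.
#'
#' @param events A `detection_events` data frame whose `time` column holds
#'   seconds since `start`, or a POSIXct `time` column.
#' @param start POSIXct start of the recording calendar (UTC recommended).
#' @param end POSIXct end of the calendar; events outside `[start, end]` are
#'   an error.
#' @param review Optional data frame with columns `time` and `confirmed`
#'   (logical): the analyst-review record. Detections within half an hour of
#'   an unconfirmed review entry are dropped; absent review accepts all.
#' @return A `presence_series`: list with `hourly` (data frame `date`,
#'   `hour`, `present`) and `daily` (data frame `date`, `hours_with_song`).
#' @export
aggregate_presence <- function(events, start, end, review = NULL) {
  stopifnot(inherits(start, "POSIXct"), inherits(end, "POSIXct"))
  tt <- if (inherits(events$time, "POSIXct")) events$time
        else start + events$time
  if (length(tt) && (min(tt) < start || max(tt) > end)) {
    stop("events outside the recording calendar", call. = FALSE)
  }
  if (!is.null(review)) {
    bad <- review$time[!review$confirmed]
    if (length(bad) && length(tt)) {
      drop <- vapply(tt, function(t1)
        any(abs(as.numeric(difftime(t1, bad, units = "secs"))) <= 1800),
        logical(1))
      tt <- tt[!drop]
    }
  }
  hours <- seq(trunc(start, "hours"), trunc(end, "hours"), by = "hour")
  key <- format(hours, "%Y-%m-%d %H", tz = "UTC")
  present <- key %in% unique(format(tt, "%Y-%m-%d %H", tz = "UTC"))
  hourly <- data.frame(date = format(hours, "%Y-%m-%d", tz = "UTC"),
                       hour = as.integer(format(hours, "%H", tz = "UTC")),
                       present = present)
  daily <- stats::aggregate(present ~ date, hourly, sum)
  names(daily) <- c("date", "hours_with_song")
  structure(list(hourly = hourly, daily = daily),
            class = "presence_series")
}

#' @export
print.presence_series <- function(x, ...) {
  cat(sprintf("Presence series: %d days, %d song-hours (%d days with song)\n",
              nrow(x$daily), sum(x$hourly$present),
              sum(x$daily$hours_with_song > 0)))
  invisible(x)
}

#' @export
plot.presence_series <- function(x, ...) {
  graphics::barplot(x$daily$hours_with_song,
                    names.arg = x$daily$date, las = 2, cex.names = 0.6,
                    ylab = "hours per day with song", ...)
  invisible(x)
}

#' Detector error rates against a known-truth presence series
#'
#' The false-negative rate is the fraction of true song-hours the detector
#' missed; the false-positive rate is the fraction of true no-song hours
#' with a (spurious) detection. Both series must share the same calendar.
#'
#' @param detected,truth `presence_series` objects (or their `hourly` data
#'   frames) on identical calendars.
#' @return List with `false_negative_rate`, `false_positive_rate` (each `NA`
#'   if undefined), and the underlying counts.
#' @export
evaluate_detector <- function(detected, truth) {
  hd <- if (inherits(detected, "presence_series")) detected$hourly else detected
  ht <- if (inherits(truth, "presence_series")) truth$hourly else truth
  if (nrow(hd) != nrow(ht) ||
      !all(hd$date == ht$date & hd$hour == ht$hour)) {
    stop("detected and truth series must share an identical calendar",
         call. = FALSE)
  }
  n_true <- sum(ht$present)
  n_absent <- sum(!ht$present)
  fn <- sum(ht$present & !hd$present)
  fp <- sum(!ht$present & hd$present)
  list(false_negative_rate = if (n_true > 0) fn / n_true else NA_real_,
       false_positive_rate = if (n_absent > 0) fp / n_absent else NA_real_,
       n_true_song_hours = n_true, n_missed = fn, n_false_alarms = fp)
}
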