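#' Gap policy for track assembly
#'
#' Locations arrive every 60-120 s while the singer is audible; short gaps
#' of a few minutes occur when song becomes faint (e.g. the singer
#' surfacing), and longer dropouts when ship noise masks a channel. Gaps up
#' to `split_bound` are kept inside one track (flagged when longer than
#' `short_gap`); longer gaps end the track and start a new one.
#'
#' @param cadence Expected location cadence in seconds.
#' @param short_gap Gaps longer than this (s) are flagged.
#' @param split_bound Gaps longer than this (s) split the track.
#' @return A `gap_policy` list.
#' @export
gap_policy <- function(cadence = 90, short_gap = 150, split_bound = 1200) {
  if (!(split_bound > short_gap && short_gap > cadence)) {
    stop("need split_bound > short_gap > cadence", call. = FALSE)
  }
  structure(list(cadence = cadence, short_gap = short_gap,
                 split_bound = split_bound), class = "gap_policy")
}

new_whale_track <- function(df, session, smoothed = FALSE, season = NA) {
  structure(df, session = session, smoothed = smoothed, season = season,
            class = c("whale_track", "data.frame"))
}

#' Assemble QC-passed locations into tracks
#'
#' A track is the complete, time-ordered collection of locations from one
#' song session, with moves between locations treated as straight lines.
#' Estimates that failed quality control are excluded; gaps are handled per
#' the [gap_policy()].
#'
#' @param estimates A `location_set` (or data frame with columns `session`,
#'   `t`, `x`, `y` and optionally `qc`).
#' @param policy A [gap_policy()].
#' @param season Optional season label attached to the tracks.
#' @return A list of `whale_track` objects (possibly several per session if
#'   long gaps split it); sessions with fewer than 2 usable points are
#'   reported via a message and dropped.
#' @export
build_tracks <- function(estimates, policy = gap_policy(), season = NA) {
  est <- as.data.frame(estimates)
  if (!is.null(est$qc)) est <- est[est$qc == "pass", , drop = FALSE]
  if (is.null(est$session)) est$session <- "S1"
  tracks <- list()
  for (sid in unique(est$session)) {
    e <- est[est$session == sid, , drop = FALSE]
    e <- e[order(e$t), , drop = FALSE]
    e <- e[!duplicated(e$t), , drop = FALSE]
    if (nrow(e) < 2L) {
      message(sprintf("session %s: fewer than 2 usable locations; no track",
                      sid))
      next
    }
    gaps <- diff(e$t)
    piece <- cumsum(c(0, gaps > policy$split_bound))
    npieces <- max(piece) + 1L
    for (pc in unique(piece)) {
      d <- e[piece == pc, c("t", "x", "y"), drop = FALSE]
      if (nrow(d) < 2L) {
        message(sprintf("session %s piece %d: fewer than 2 locations; dropped",
                        sid, pc + 1L))
        next
      }
      d$gap_before <- c(FALSE, diff(d$t) > policy$short_gap)
      rownames(d) <- NULL
      lab <- if (npieces > 1L) sprintf("%s.%d", sid, pc + 1L) else sid
      tracks[[lab]] <- new_whale_track(d, session = lab, season = season)
    }
  }
  tracks
}

#' Moving-average track smoothing
#'
#' Replaces each location with the mean of the `window` surrounding
#' locations centered on it, timestamped at the median (center) time of the
#' window. With the default `ends = "trim"`, the first and last
#' `(window - 1) / 2` points are dropped (no partial windows), trading a
#' slight reduction in time resolution for suppression of localization
#' "wiggle"; `ends = "shrink"` instead shrinks the window symmetrically near
#' the ends so no points are lost. Because each smoothed increment is a mean
#' of raw increments, the smoothed total path length never exceeds the raw
#' one.
#'
#' @param track A `whale_track` (or data frame with `t`, `x`, `y`).
#' @param window Odd window length >= 3; default the 5-point window.
#' @param ends End handling, `"trim"` or `"shrink"`.
#' @return A smoothed `whale_track`. A track shorter than `window` is
#'   returned unsmoothed with a warning.
#' @examples
#' trk <- data.frame(t = 0:9 * 60, x = (0:9) * 30, y = 0)
#' smooth_track(trk)
#' @export
smooth_track <- function(track, window = 5, ends = c("trim", "shrink")) {
  ends <- match.arg(ends)
  if (window < 3 || window %% 2 == 0) {
    stop("`window` must be odd and >= 3", call. = FALSE)
  }
  n <- nrow(track)
  if (n < window) {
    warning("track shorter than the smoothing window; returned unsmoothed",
            call. = FALSE)
    return(track)
  }
  h <- (window - 1L) / 2L
  sx <- numeric(n); sy <- numeric(n)
  for (i in seq_len(n)) {
    k <- if (ends == "shrink") min(h, i - 1L, n - i) else h
    idx <- (i - k):(i + k)
    idx <- idx[idx >= 1L & idx <= n]
    sx[i] <- mean(track$x[idx])
    sy[i] <- mean(track$y[idx])
  }
  keep <- if (ends == "trim") (h + 1L):(n - h) else seq_len(n)
  out <- data.frame(t = track$t[keep], x = sx[keep], y = sy[keep])
  if (!is.null(track$gap_before)) out$gap_before <- track$gap_before[keep]
  rownames(out) <- NULL
  new_whale_track(out,
                  session = attr(track, "session") %||% "S1",
                  smoothed = TRUE,
                  season = attr(track, "season") %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.whale_track <- function(x, ...) {
  cat(sprintf("Whale track %s%s: %d locations over %.2f h\n",
              attr(x, "session") %||% "?",
              if (isTRUE(attr(x, "smoothed"))) " (smoothed)" else " (raw)",
              nrow(x), diff(range(x$t)) / 3600))
  invisible(x)
}

#' @export
plot.whale_track <- function(x, add = FALSE, col = "firebrick", ...) {
  if (!add) {
    graphics::plot(x$x, x$y, type = "n", asp = 1, xlab = "x (m)",
                   ylab = "y (m)", ...)
  }
  graphics::lines(x$x, x$y, col = col)
  graphics::points(x$x, x$y, pch = 16, cex = 0.5, col = col)
  graphics::points(x$x[1], x$y[1], pch = 1, cex = 1.2, col = col)
  invisible(x)
}

#' @export
summary.whale_track <- function(object, ...) track_stats(object)

#' Read/write tracks as CSV, and GeoJSON export
#'
#' The CSV schema is `session, t, x, y, smoothed, gap_before`. GeoJSON
#' export writes each track as a LineString in the local planar coordinates
#' (for mapping pipelines that handle the projection).
#'
#' @param tracks A list of `whale_track` objects.
#' @param file Output path.
#' @param seed Optional seed recorded in the CSV header.
#' @return `read_tracks_csv()` returns a list of `whale_track`s.
#' @export
write_tracks_csv <- function(tracks, file, seed = NULL) {
  rows <- lapply(tracks, function(tr) {
    data.frame(session = attr(tr, "session") %||% "S1", t = tr$t,
               x = tr$x, y = tr$y,
               smoothed = isTRUE(attr(tr, "smoothed")),
               gap_before = tr$gap_before %||% FALSE)
  })
  write_table_with_header(do.call(rbind, rows), file,
                          file_header_line(seed))
  invisible(file)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(file) {
  if (!file.exists(file)) {
    stop(sprintf("missing tracks file: %s", file), call. = FALSE)
  }
  d <- read_table_with_header(file)
  lapply(split(d, d$session), function(e) {
    new_whale_track(e[, c("t", "x", "y", "gap_before")],
                    session = e$session[1], smoothed = any(e$smoothed))
  })
}

#' @rdname write_tracks_csv
#' @export
tracks_geojson <- function(tracks, file) {
  feats <- lapply(tracks, function(tr) {
    list(type = "Feature",
         properties = list(session = attr(tr, "session") %||% "S1",
                           smoothed = isTRUE(attr(tr, "smoothed"))),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(tr)), function(i)
                           c(tr$x[i], tr$y[i]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
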