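#' Hydrophone array geometry and clock synchronization
#'
#' Constructs the description of a bottom-mounted recorder array: sensor
#' positions in a local planar east/north coordinate frame (meters from an
#' arbitrary reference origin), sensor depths, the common sampling rate, and
#' per-sensor clock-synchronization measurements taken immediately before
#' deployment and upon retrieval.
#'
#' Coordinates are planar because typical array spans (tens of km) make the
#' projection error negligible; localization downstream is horizontal-only.
#'
#' @param x,y Sensor easting/northing in meters.
#' @param depth Sensor depths in meters (positive down).
#' @param id Sensor identifiers; defaults to `1:n`.
#' @param sample_rate Sampling rate in Hz shared by all channels.
#' @param clock_sync Optional data frame with columns `id`, `offset_start`,
#'   `offset_end`, `span`: recorder-clock offsets (seconds, recorded minus
#'   true time) measured at deployment and retrieval, and the deployment span
#'   in seconds. `NULL` means perfectly synchronized clocks.
#' @return An object of class `hydrophone_array`.
#' @examples
#' arr <- hydrophone_array(x = c(0, 5000, 2500), y = c(0, 0, 4300),
#'                         depth = c(60, 80, 100))
#' arr
#' @export
hydrophone_array <- function(x, y, depth, id = seq_along(x),
                             sample_rate = 2000, clock_sync = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(depth) == n, length(id) == n)
  if (n < 3L) stop("an array needs at least 3 sensors", call. = FALSE)
  stop_if_not_positive(sample_rate, "sample_rate")
  d <- as.matrix(stats::dist(cbind(x, y)))
  if (any(d[upper.tri(d)] <= 0)) {
    stop("all pairwise horizontal sensor separations must be > 0", call. = FALSE)
  }
  if (is.null(clock_sync)) {
    clock_sync <- data.frame(id = id, offset_start = 0, offset_end = 0,
                             span = Inf)
  } else {
    stopifnot(all(c("id", "offset_start", "offset_end", "span") %in%
                    names(clock_sync)))
    clock_sync <- clock_sync[match(id, clock_sync$id), , drop = FALSE]
    if (anyNA(clock_sync$id)) stop("clock_sync must cover every sensor id")
    if (any(clock_sync$span <= 0)) {
      stop("clock_sync deployment span must be > 0", call. = FALSE)
    }
  }
  structure(
    list(sensors = data.frame(id = id, x = x, y = y, depth = depth),
         sample_rate = sample_rate,
         clock_sync = clock_sync),
    class = "hydrophone_array")
}

#' @export
print.hydrophone_array <- function(x, ...) {
  s <- x$sensors
  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  sep <- d[upper.tri(d)]
  cat(sprintf("Hydrophone array: %d sensors, fs = %g Hz\n", nrow(s),
              x$sample_rate))
  cat(sprintf("  spacing %.1f-%.1f km, depths %.0f-%.0f m\n",
              min(sep) / 1000, max(sep) / 1000, min(s$depth), max(s$depth)))
  drift <- abs(x$clock_sync$offset_end - x$clock_sync$offset_start)
  if (any(drift > 0)) {
    cat(sprintf("  clock drift up to %.3f s over deployment\n", max(drift)))
  } else {
    cat("  clocks synchronized (no drift)\n")
  }
  invisible(x)
}

#' Recorder clock-drift offset and correction
#'
#' Autonomous recorders drift slowly against true time; the offset is
#' measured at deployment and retrieval and assumed to grow linearly in
#' between. `drift_offset()` gives the offset (recorded minus true time) at a
#' true time; `correct_clock_drift()` inverts the mapping, converting a
#' recorded timestamp back to true time so that residual offsets at both
#' synchronization endpoints are zero.
#'
#' @param t True time in seconds since deployment (for `drift_offset`) or
#'   recorded time (for `correct_clock_drift`).
#' @param offset_start,offset_end Measured clock offsets (s) at deployment
#'   start and end.
#' @param span Deployment span in seconds; must be > 0 when the two offsets
#'   differ.
#' @return Numeric vector: the offset in seconds, or the corrected (true)
#'   timestamps.
#' @examples
#' correct_clock_drift(100, 0, 0, 1000)    # no drift: unchanged
#' t_true <- 500
#' t_rec <- t_true + drift_offset(t_true, 0, 1, 1000)
#' t_rec - t_true                           # 0.5 s offset at mid-deployment
#' correct_clock_drift(t_rec, 0, 1, 1000)   # recovers 500
#' @export
drift_offset <- function(t, offset_start, offset_end, span) {
  if (span <= 0) stop("deployment span must be > 0", call. = FALSE)
  offset_start + (offset_end - offset_start) * t / span
}

#' @rdname drift_offset
#' @export
correct_clock_drift <- function(t, offset_start, offset_end, span) {
  if (span <= 0) stop("deployment span must be > 0", call. = FALSE)
  slope <- (offset_end - offset_start) / span
  (t - offset_start) / (1 + slope)
}

#' Read/write array geometry as CSV
#'
#' Columns: `id`, `x`, `y`, `depth`, and optionally `offset_start`,
#' `offset_end`, `span` for clock synchronization.
#'
#' @param file Path to a CSV file.
#' @param array A `hydrophone_array`.
#' @param sample_rate Sampling rate used when reading (not stored in the CSV).
#' @param seed Optional seed recorded in the file header.
#' @return `read_array_geometry()` returns a `hydrophone_array`.
#' @export
read_array_geometry <- function(file, sample_rate = 2000) {
  if (!file.exists(file)) {
    stop(sprintf("missing geometry file: %s", file), call. = FALSE)
  }
  g <- read_table_with_header(file)
  cs <- NULL
  if (all(c("offset_start", "offset_end", "span") %in% names(g))) {
    cs <- g[, c("id", "offset_start", "offset_end", "span")]
  }
  hydrophone_array(g$x, g$y, g$depth, id = g$id, sample_rate = sample_rate,
                   clock_sync = cs)
}

#' @rdname read_array_geometry
#' @export
write_array_geometry <- function(array, file, seed = NULL) {
  g <- cbind(array$sensors,
             array$clock_sync[, c("offset_start", "offset_end", "span")])
  write_table_with_header(g, file, file_header_line(seed))
  invisible(file)
}
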