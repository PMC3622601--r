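#' Step-level movement metrics
#'
#' A step is the straight-line move between two sequential track locations.
#' For each step: Euclidean distance (m), time interval (s), absolute
#' heading (radians from the x axis), relative turning angle (wrapped
#' heading change, in `(-pi, pi]`), and net displacement from the track
#' start at the step's end. Turning angles across zero-length steps are
#' undefined: they are returned as `NA` and counted in the
#' `n_undefined_turns` attribute rather than set to zero, which would bias
#' angle distributions toward straightness.
#'
#' @param track A `whale_track` or data frame with `t`, `x`, `y`; at least
#'   2 points, strictly increasing unique times.
#' @return A `step_metrics` data frame with one row per step: `t0`, `t1`,
#'   `dt`, `distance`, `heading`, `turning_angle`, `net_displacement`.
#' @examples
#' trk <- data.frame(t = c(0, 100), x = c(0, 3), y = c(0, 4))
#' step_metrics(trk)  # one 5 m step over 100 s
#' @export
step_metrics <- function(track) {
  n <- nrow(track)
  if (n < 2L) stop("a track needs at least 2 points", call. = FALSE)
  if (anyDuplicated(track$t)) {
    stop("duplicate timestamps in track", call. = FALSE)
  }
  o <- order(track$t)
  t <- track$t[o]; x <- track$x[o]; y <- track$y[o]
  dx <- diff(x); dy <- diff(y)
  dist <- sqrt(dx^2 + dy^2)
  heading <- ifelse(dist > 0, atan2(dy, dx), NA_real_)
  turn <- c(NA_real_, wrap_angle(diff(heading)))
  out <- data.frame(t0 = t[-n], t1 = t[-1], dt = diff(t), distance = dist,
                    heading = heading, turning_angle = turn,
                    net_displacement = sqrt((x[-1] - x[1])^2 +
                                              (y[-1] - y[1])^2))
  structure(out, n_undefined_turns = sum(is.na(turn[-1])),
            class = c("step_metrics", "data.frame"))
}

#' Whole-track movement statistics
#'
#' Sums the stepwise measurements into the four whole-track parameters —
#' duration (h), total distance traveled (km), net displacement (km),
#' average speed (km/h, distance over duration) — plus the straightness
#' index (SI): net displacement from start to end divided by total distance
#' traveled. A whale traveling in a straight line has SI = 1; an
#' increasingly meandering path drives SI toward 0. SI lies in `[0, 1]` by
#' the triangle inequality.
#'
#' @param track A `whale_track` or data frame with `t`, `x`, `y` (internal
#'   units meters/seconds; reported in km, h, km/h).
#' @return A `track_stats` object: list with `session`, `season`, `n`,
#'   `duration_h`, `distance_km`, `net_displacement_km`, `speed_kmh`,
#'   `straightness` (NA with a flag if the track has zero length) and
#'   `smoothed`.
#' @examples
#' trk <- data.frame(t = c(0, 60, 120), x = c(0, 1, 2), y = c(0, 1, 0))
#' track_stats(trk)$straightness  # 2 / (2 * sqrt(2)) = 0.7071
#' @export
track_stats <- function(track) {
  sm <- step_metrics(track)
  dur <- sum(sm$dt)
  if (dur <= 0) stop("track duration must be positive", call. = FALSE)
  dist <- sum(sm$distance)
  disp <- sm$net_displacement[nrow(sm)]
  structure(list(session = attr(track, "session") %||% NA,
                 season = attr(track, "season") %||% NA,
                 n = nrow(track),
                 duration_h = dur / 3600,
                 distance_km = dist / 1000,
                 net_displacement_km = disp / 1000,
                 speed_kmh = dist / dur * 3.6,
                 straightness = if (dist > 0) disp / dist else NA_real_,
                 zero_length = dist <= 0,
                 smoothed = isTRUE(attr(track, "smoothed"))),
            class = "track_stats")
}

#' @export
print.track_stats <- function(x, ...) {
  cat(sprintf("Track statistics%s:\n",
              if (is.na(x$session)) "" else paste0(" (", x$session, ")")))
  cat(sprintf("  duration %.2f h, distance %.2f km, net displacement %.2f km\n",
              x$duration_h, x$distance_km, x$net_displacement_km))
  cat(sprintf("  average speed %.2f km/h, straightness index %s\n",
              x$speed_kmh,
              if (is.na(x$straightness)) "undefined (zero-length track)"
              else sprintf("%.2f", x$straightness)))
  invisible(x)
}

#' Table of whole-track statistics for a set of tracks
#'
#' @param tracks List of `whale_track` objects.
#' @return Data frame with one row per track: `session`, `season`,
#'   `duration_h`, `distance_km`, `speed_kmh`, `net_displacement_km`,
#'   `straightness`.
#' @export
track_stats_table <- function(tracks) {
  rows <- lapply(tracks, function(tr) {
    s <- track_stats(tr)
    data.frame(session = as.character(s$session), season = s$season,
               duration_h = s$duration_h, distance_km = s$distance_km,
               speed_kmh = s$speed_kmh,
               net_displacement_km = s$net_displacement_km,
               straightness = s$straightness)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

TRACK_PARAMS <- c("distance_km", "duration_h", "speed_kmh",
                  "net_displacement_km", "straightness")

#' Spearman correlations between track parameters
#'
#' Non-parametric Spearman rank correlations for every pair of whole-track
#' parameters, with two-sided p-values. Constant parameters have undefined
#' rank correlation and are flagged `NA`.
#'
#' @param stats_table A [track_stats_table()] data frame (>= 3 tracks).
#' @param params Parameter columns to correlate.
#' @return A `track_param_cor` object: list with matrices `rho` and `p`,
#'   the flagged `constant` parameters, and `n`.
#' @export
correlate_params <- function(stats_table, params = TRACK_PARAMS) {
  stopifnot(all(params %in% names(stats_table)))
  if (nrow(stats_table) < 3L) {
    stop("need at least 3 tracks to correlate parameters", call. = FALSE)
  }
  k <- length(params)
  rho <- matrix(NA_real_, k, k, dimnames = list(params, params))
  pv <- rho
  diag(rho) <- 1
  constant <- params[vapply(params, function(p)
    stats::sd(stats_table[[p]], na.rm = TRUE) == 0, logical(1))]
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (params[a] %in% constant || params[b] %in% constant) next
    ct <- suppressWarnings(
      stats::cor.test(stats_table[[params[a]]], stats_table[[params[b]]],
                      method = "spearman", exact = FALSE))
    rho[a, b] <- rho[b, a] <- unname(ct$estimate)
    pv[a, b] <- pv[b, a] <- ct$p.value
  }
  structure(list(rho = rho, p = pv, constant = constant,
                 n = nrow(stats_table)),
            class = "track_param_cor")
}

#' @export
print.track_param_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman rank correlations over %d tracks\n", x$n))
  print(round(x$rho, digits))
  if (length(x$constant)) {
    cat("constant (undefined):", paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}

# Welch / pooled two-sample comparison of one numeric vector by 2-level group.
two_group_test <- function(value, group, var_equal = FALSE) {
  g <- split(value, group)
  if (length(g) != 2L) stop("need exactly two groups", call. = FALSE)
  if (any(lengths(g) < 2L)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (all(vapply(g, stats::sd, numeric(1)) == 0)) {
    stop("zero variance in both groups; comparison undefined", call. = FALSE)
  }
  tt <- stats::t.test(g[[1]], g[[2]], var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean = vapply(g, mean, numeric(1)),
       sd = vapply(g, stats::sd, numeric(1)),
       n = lengths(g))
}

#' Seasonal comparison of track parameters and song occurrence
#'
#' For each whole-track parameter, compares the two seasons with a
#' two-sample t-test: Welch's unequal-variance test (with
#' Welch-Satterthwaite degrees of freedom) by default, and the
#' pooled-variance variant alongside it. Optionally also compares daily
#' song occurrence (hours per day with song) between seasons with a Welch
#' test. No multiple-testing correction is applied across the parameters;
#' the printed report says so.
#'
#' @param stats_table A [track_stats_table()] with a 2-level `season`
#'   column.
#' @param params Parameter columns to compare.
#' @param presence Optional data frame with columns `season` and
#'   `hours_with_song` (one row per recording day).
#' @return A `seasonal_tests` object: per-parameter Welch and pooled
#'   results with group means, SDs and ns, plus the optional presence test.
#' @export
seasonal_compare <- function(stats_table, params = TRACK_PARAMS,
                             presence = NULL) {
  stopifnot("season" %in% names(stats_table))
  seasons <- sort(unique(as.character(stats_table$season)))
  if (length(seasons) != 2L) {
    stop("`stats_table$season` must have exactly two levels", call. = FALSE)
  }
  per_param <- lapply(params, function(p) {
    list(parameter = p,
         welch = two_group_test(stats_table[[p]], stats_table$season),
         pooled = two_group_test(stats_table[[p]], stats_table$season,
                                 var_equal = TRUE))
  })
  names(per_param) <- params
  presence_test <- NULL
  if (!is.null(presence)) {
    presence_test <- two_group_test(presence$hours_with_song,
                                    presence$season)
  }
  structure(list(seasons = seasons, parameters = per_param,
                 presence = presence_test),
            class = "seasonal_tests")
}

#' @export
print.seasonal_tests <- function(x, ...) {
  cat(sprintf("Seasonal comparison: %s vs %s\n", x$seasons[1], x$seasons[2]))
  for (pp in x$parameters) {
    w <- pp$welch
    cat(sprintf(
      "  %-20s %s %.2f+/-%.2f (n=%d) vs %.2f+/-%.2f (n=%d); Welch t=%.2f df=%.1f p=%.3g\n",
      pp$parameter, "", w$mean[1], w$sd[1], w$n[1], w$mean[2], w$sd[2],
      w$n[2], w$t, w$df, w$p))
  }
  if (!is.null(x$presence)) {
    w <- x$presence
    cat(sprintf(
      "  hours/day with song: %.1f+/-%.2f vs %.1f+/-%.2f; Welch t=%.2f df=%.1f p=%.3g\n",
      w$mean[1], w$sd[1], w$mean[2], w$sd[2], w$t, w$df, w$p))
  }
  cat("  (no multiple-testing correction applied across parameters)\n")
  invisible(x)
}

# Position on a track at time tt by linear interpolation between locations.
interp_position <- function(track, tt) {
  c(x = stats::approx(track$t, track$x, xout = tt)$y,
    y = stats::approx(track$t, track$y, xout = tt)$y)
}

#' Two-singer interaction segmentation
#'
#' When two singers are tracked simultaneously, each singer's track is split
#' into an "alone" period (singing individually) and a "both" period (both
#' singing), with the segment boundary at the overlap interval endpoints;
#' positions at the boundaries are interpolated so the segments partition
#' each track exactly. Whole-track statistics are computed per segment, and
#' the separation between the singers is measured at the start and end of
#' the overlap.
#'
#' @param track_a,track_b `whale_track` objects whose time spans both cover
#'   `overlap`.
#' @param overlap Numeric `c(start, end)` of the simultaneous-song interval
#'   (seconds, shared timeline).
#' @return A `segmented_pair`: per singer, `track_stats` for the `alone`
#'   and `both` segments (`NA` where a segment has fewer than 2 points),
#'   plus `separation_start_km` and `separation_end_km`.
#' @export
pair_interaction <- function(track_a, track_b, overlap) {
  stopifnot(length(overlap) == 2L, overlap[1] < overlap[2])
  for (tr in list(track_a, track_b)) {
    if (overlap[1] < min(tr$t) || overlap[2] > max(tr$t)) {
      stop("overlap interval must lie within both tracks' time spans",
           call. = FALSE)
    }
  }
  seg <- function(track, lo, hi) {
    keep <- track$t >= lo & track$t <= hi
    d <- data.frame(t = track$t[keep], x = track$x[keep], y = track$y[keep])
    # interpolated boundary points so segments partition the track in time
    for (bt in c(lo, hi)) {
      if (bt >= min(track$t) && bt <= max(track$t) && !(bt %in% d$t)) {
        p <- interp_position(track, bt)
        d <- rbind(d, data.frame(t = bt, x = p["x"], y = p["y"]))
      }
    }
    d <- d[order(d$t), , drop = FALSE]
    if (nrow(d) < 2L || diff(range(d$t)) <= 0) return(NULL)
    new_whale_track(d, session = attr(track, "session") %||% "S1")
  }
  singer_segments <- function(track) {
    both <- seg(track, overlap[1], overlap[2])
    pre <- seg(track, min(track$t), overlap[1])
    post <- seg(track, overlap[2], max(track$t))
    alone <- if (!is.null(pre) && !is.null(post)) {
      # singer sang alone on both sides; keep the longer period
      if (diff(range(pre$t)) >= diff(range(post$t))) pre else post
    } else pre %||% post
    list(alone = if (is.null(alone)) NA else track_stats(alone),
         both = if (is.null(both)) NA else track_stats(both))
  }
  pa <- interp_position(track_a, overlap[1])
  pb <- interp_position(track_b, overlap[1])
  qa <- interp_position(track_a, overlap[2])
  qb <- interp_position(track_b, overlap[2])
  structure(list(singer_a = singer_segments(track_a),
                 singer_b = singer_segments(track_b),
                 overlap = overlap,
                 separation_start_km = sqrt(sum((pa - pb)^2)) / 1000,
                 separation_end_km = sqrt(sum((qa - qb)^2)) / 1000),
            class = "segmented_pair")
}

#' @export
print.segmented_pair <- function(x, ...) {
  fmt <- function(s) {
    if (!inherits(s, "track_stats")) return("  (not applicable)\n")
    sprintf("  %.2f h, %.2f km, %.2f km/h, SI %s\n", s$duration_h,
            s$distance_km, s$speed_kmh,
            if (is.na(s$straightness)) "NA" else sprintf("%.2f",
                                                         s$straightness))
  }
  cat(sprintf("Two-singer interaction (overlap %.0f-%.0f s; separation %.1f -> %.1f km)\n",
              x$overlap[1], x$overlap[2], x$separation_start_km,
              x$separation_end_km))
  cat("Singer A alone:\n", fmt(x$singer_a$alone))
  cat("Singer A both :\n", fmt(x$singer_a$both))
  cat("Singer B alone:\n", fmt(x$singer_b$alone))
  cat("Singer B both :\n", fmt(x$singer_b$both))
  invisible(x)
}
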