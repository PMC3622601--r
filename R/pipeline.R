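#' Default pipeline configuration
#'
#' A single nested list (serializable to YAML) with one section per stage.
#' All paths are relative to the pipeline output directory. `config show`
#' in the command-line wrapper prints exactly this structure.
#'
#' @param seed Integer seed controlling every stochastic stage.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    paths = list(recording = "recording.wav", geometry = "geometry.csv",
                 selections = "selections.tsv", truth = "truth.csv",
                 locations = "locations.csv", tracks = "tracks.csv",
                 stats = "track_stats.csv", correlations = "correlations.csv",
                 presence = "presence.csv", detections = "detections.tsv",
                 calibration = "calibration.json",
                 calibration_sweeps = "calibration_sweeps.csv",
                 report = "report.json"),
    array = list(x = c(0, 6000, 12000, 3000, 9000, 0, 6000, 12000, 3000,
                       9000),
                 y = c(0, 0, 0, 5200, 5200, 10400, 10400, 10400, 15600,
                       15600),
                 depth = rep(60, 10), sample_rate = 2000),
    simulate = list(nominal_speed = 2, duration = 1, step_dt = 60,
                    turn_concentration = 5, unit_interval = 90,
                    unit = list(kind = "sweep", f0 = 100, f1 = 400,
                                duration = 1.5, source_level = 165),
                    snr_db = 30, sound_speed = 1480, source_depth = 15,
                    start = c(6000, 7800)),
    detect = list(threshold = 0.5, window = 256, overlap = 0.75),
    grid = list(margin = 5000, resolution = 200, refine_factor = 10,
                refine_levels = 2),
    localize = list(sound_speed = 1480, qc_tolerance = 0.010,
                    min_pairs = 3),
    track = list(cadence = 90, short_gap = 150, split_bound = 1200,
                 smooth_window = 5),
    calibrate = list(n_positions = 5, n_per_position = 10,
                     arrival_jitter_sd = 0.02))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("missing config file: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  # YAML 1.1 parses a bare `y:` key as boolean TRUE; restore the coordinate
  if (!is.null(config$array) && "TRUE" %in% names(config$array)) {
    names(config$array)[names(config$array) == "TRUE"] <- "y"
  }
  base <- default_config()
  modifyList(base, config)
}

#' Run the tracking pipeline
#'
#' Chains the stages on synthetic data with a shared configuration and a
#' single deterministic seed: `simulate` renders the recording and writes
#' the WAV, geometry, ground truth and selection table; `detect` runs the
#' template detector over the recording; `localize` estimates a position
#' for every selection; `track` assembles and smooths tracks; `stats`
#' writes whole-track statistics and their rank correlations; `calibrate`
#' runs the playback calibration experiment. `all` chains
#' simulate, localize, track and stats. Every output file's header records
#' the seed and a hash of the configuration. A missing upstream artifact
#' stops with an error naming the file.
#'
#' @param steps Character vector of stages, or `"all"`.
#' @param config Configuration list or path to a YAML file; merged over
#'   [default_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the paths of the artifacts written.
#' @export
run_pipeline <- function(steps = "all", config = default_config(),
                         outdir = tempfile("songtrack_")) {
  cfg <- load_config(config)
  hash <- config_hash(cfg)
  seed <- cfg$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(key) file.path(outdir, cfg$paths[[key]])
  if (identical(steps, "all")) steps <- c("simulate", "localize", "track",
                                          "stats")
  header <- file_header_line(seed, hash)
  artifacts <- list()
  array <- hydrophone_array(cfg$array$x, cfg$array$y, cfg$array$depth,
                            sample_rate = cfg$array$sample_rate)

  if ("simulate" %in% steps) {
    sc <- cfg$simulate
    trk <- simulate_track(sc$nominal_speed, sc$duration, sc$step_dt,
                          sc$turn_concentration, start = unlist(sc$start),
                          seed = seed)
    sched <- regular_schedule(trk, interval = sc$unit_interval,
                              kind = sc$unit$kind, f0 = sc$unit$f0,
                              f1 = sc$unit$f1, duration = sc$unit$duration,
                              source_level = sc$unit$source_level)
    rcfg <- sim_config(sound_speed = sc$sound_speed, snr_db = sc$snr_db,
                       source_depth = sc$source_depth, seed = seed + 1)
    rec <- render_recording(array, trk, sched, rcfg)
    write_wav(rec$wave, rec$fs, pth("recording"))
    write_array_geometry(array, pth("geometry"), seed = seed)
    write_table_with_header(rec$truth, pth("truth"), header)
    write_selection_table(selections_from_truth(rec), pth("selections"),
                          seed = seed)
    artifacts[c("recording", "geometry", "truth", "selections")] <-
      lapply(c("recording", "geometry", "truth", "selections"), pth)
  }

  read_recording <- function() {
    wv <- read_wav(pth("recording"))
    arr <- read_array_geometry(pth("geometry"), sample_rate = wv$fs)
    structure(list(wave = wv$wave, fs = wv$fs, array = arr),
              class = "array_recording")
  }

  if ("detect" %in% steps) {
    rec <- read_recording()
    tpl <- song_template(fs = rec$fs, kind = cfg$simulate$unit$kind,
                         f0 = cfg$simulate$unit$f0, f1 = cfg$simulate$unit$f1,
                         duration = cfg$simulate$unit$duration,
                         params = spectrogram_params(
                           window = cfg$detect$window,
                           overlap = cfg$detect$overlap,
                           fft = cfg$detect$window))
    ev <- detect_template(rec$wave, tpl, fs = rec$fs,
                          threshold = cfg$detect$threshold)
    det <- data.frame(Selection = seq_len(nrow(ev)),
                      `Begin Time (s)` = ev$time - tpl$duration / 2,
                      `End Time (s)` = ev$time + tpl$duration / 2,
                      `Low Freq (Hz)` = min(cfg$simulate$unit$f0,
                                            cfg$simulate$unit$f1),
                      `High Freq (Hz)` = max(cfg$simulate$unit$f0,
                                             cfg$simulate$unit$f1),
                      Channel = ev$channel, Score = ev$score,
                      check.names = FALSE)
    write_selection_table(det, pth("detections"), seed = seed)
    start <- as.POSIXct("2009-04-01 00:00:00", tz = "UTC")
    pres <- aggregate_presence(ev, start,
                               start + nrow(rec$wave) / rec$fs)
    write_table_with_header(pres$hourly, pth("presence"), header)
    artifacts[c("detections", "presence")] <-
      lapply(c("detections", "presence"), pth)
  }

  if ("localize" %in% steps) {
    if (!file.exists(pth("recording"))) {
      stop(sprintf("missing recording file: %s", pth("recording")),
           call. = FALSE)
    }
    rec <- read_recording()
    sels <- read_selection_table(pth("selections"))
    grid <- search_grid(rec$array, margin = cfg$grid$margin,
                        resolution = cfg$grid$resolution,
                        refine_factor = cfg$grid$refine_factor,
                        refine_levels = cfg$grid$refine_levels)
    locs <- localize_selections(sels, rec, grid = grid,
                                sound_speed = cfg$localize$sound_speed,
                                qc_tolerance = cfg$localize$qc_tolerance,
                                min_pairs = cfg$localize$min_pairs)
    write_table_with_header(as.data.frame(locs), pth("locations"), header)
    artifacts$locations <- pth("locations")
  }

  if ("track" %in% steps) {
    if (!file.exists(pth("locations"))) {
      stop(sprintf("missing locations file: %s", pth("locations")),
           call. = FALSE)
    }
    locs <- read_table_with_header(pth("locations"))
    pol <- gap_policy(cfg$track$cadence, cfg$track$short_gap,
                      cfg$track$split_bound)
    raw <- build_tracks(locs, pol)
    smoothed <- lapply(raw, smooth_track, window = cfg$track$smooth_window)
    write_tracks_csv(smoothed, pth("tracks"), seed = seed)
    artifacts$tracks <- pth("tracks")
  }

  if ("stats" %in% steps) {
    if (!file.exists(pth("tracks"))) {
      stop(sprintf("missing tracks file: %s", pth("tracks")), call. = FALSE)
    }
    tracks <- read_tracks_csv(pth("tracks"))
    st <- track_stats_table(tracks)
    write_table_with_header(st, pth("stats"), header)
    rep <- list(seed = seed, config_md5 = hash, n_tracks = nrow(st),
                mean_speed_kmh = mean(st$speed_kmh),
                mean_straightness = mean(st$straightness, na.rm = TRUE))
    if (nrow(st) >= 3L) {
      cp <- correlate_params(st)
      write_table_with_header(as.data.frame(cp$rho), pth("correlations"),
                              header)
      artifacts$correlations <- pth("correlations")
    }
    jsonlite::write_json(rep, pth("report"), auto_unbox = TRUE, digits = NA)
    artifacts[c("stats", "report")] <- lapply(c("stats", "report"), pth)
  }

  if ("calibrate" %in% steps) {
    cc <- cfg$calibrate
    s <- array$sensors
    ctr <- c(mean(range(s$x)), mean(range(s$y)))
    ang <- seq(0, 2 * pi, length.out = cc$n_positions + 1)[-1]
    rad <- 0.3 * min(diff(range(s$x)), diff(range(s$y)))
    pos <- data.frame(x = ctr[1] + rad * cos(ang),
                      y = ctr[2] + rad * sin(ang), depth = 15)
    ccfg <- sim_config(sound_speed = cfg$localize$sound_speed,
                       arrival_jitter_sd = cc$arrival_jitter_sd,
                       seed = seed + 2)
    pb <- simulate_calibration_playbacks(array, pos, cc$n_per_position,
                                         ccfg)
    grid <- search_grid(array, margin = cfg$grid$margin,
                        resolution = cfg$grid$resolution,
                        refine_factor = cfg$grid$refine_factor,
                        refine_levels = cfg$grid$refine_levels)
    cal <- calibrate(pb, grid = grid,
                     sound_speed = cfg$localize$sound_speed)
    write_table_with_header(cal$locations, pth("calibration_sweeps"),
                            header)
    jsonlite::write_json(
      list(seed = seed, config_md5 = hash,
           mean_error_m = cal$result$mean_error,
           sd_error_m = cal$result$sd_error,
           n_sweeps = cal$result$n_sweeps,
           n_positions = cal$result$n_positions),
      pth("calibration"), auto_unbox = TRUE, digits = NA)
    artifacts[c("calibration", "calibration_sweeps")] <-
      lapply(c("calibration", "calibration_sweeps"), pth)
  }

  invisible(c(artifacts, list(outdir = outdir)))
}
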