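# songtrack

Passive acoustic tracking of singing whales on arrays of bottom-mounted
hydrophone recorders, for marine bioacousticians and movement ecologists.
Singing humpback whales are loud enough to be heard across a whole recorder
array; the pattern of time differences of arrival (TDOAs) of one song unit
across channels pins down the singer's horizontal position, and a sequence
of such positions through a song session is an acoustic track — movement
data with no tag and no vessel.

The core estimator is **correlation-sum localization**: for a candidate
position p with horizontal ranges r_i(p) to the sensors, each channel
pair's normalized waveform cross-correlation ρ_ij is evaluated at the lag
that position predicts, and the position maximizing

    S(p) = Σ_{i<j} ρ_ij( (r_i(p) − r_j(p)) / c )

over an iteratively refined horizontal grid (200 m → 20 m → 2 m by
default) is the location estimate. Around it the package provides:

* a **synthetic-scene generator** — correlated-random-walk singer movement,
  tone/sweep song units in the 10–585 Hz band, propagation delay with
  fractional-sample placement, spreading loss, band-limited ambient noise,
  per-sensor clock drift, and playback-calibration scenes with known source
  positions;
* a **template detector** (normalized spectrogram cross-correlation) with
  hourly/daily song-presence aggregation and miss/false-alarm evaluation;
* **quality control** comparing measured pairwise peak lags against the
  lags an estimate predicts, and a **calibration** workflow reporting mean
  and SD localization error over known-position sweeps;
* **track assembly** with gap handling, the 5-point centered
  moving-average smoother, and movement statistics: step metrics, track
  duration/distance/net displacement/average speed, the straightness index
  (SI = net displacement / total distance), Spearman parameter
  correlations, Welch/pooled seasonal comparisons, and two-singer
  interaction segmentation;
* a YAML-configured pipeline (`run_pipeline()`, plus a thin CLI wrapper in
  `inst/cli/songtrack.R`) that chains the stages deterministically and
  stamps every artifact with the seed and config hash.

## Worked example

Simulate a singer crossing a ten-recorder array, localize every song unit,
and summarise the smoothed track:

```r
library(songtrack)
arr <- hydrophone_array(
  x = c(0, 6000, 12000, 3000, 9000, 0, 6000, 12000, 3000, 9000),
  y = c(0, 0, 0, 5200, 5200, 10400, 10400, 10400, 15600, 15600),
  depth = rep(60, 10))
trk <- simulate_track(nominal_speed = 2, duration = 1, step_dt = 60,
                      turn_concentration = 5, start = c(6000, 7800), seed = 1)
sched <- regular_schedule(trk, interval = 90)           # a unit every 90 s
rec <- render_recording(arr, trk, sched,
                        sim_config(snr_db = 30, source_depth = 15, seed = 2))
sels <- selections_from_truth(rec)                      # analyst's markings
locs <- localize_selections(sels, rec, grid = search_grid(arr))
summary(locs)
#> Location set: 40 estimates, 40 QC-passed (100%)
sm <- smooth_track(build_tracks(locs)[[1]])
track_stats(sm)
#> Track statistics (S1):
#>   duration 0.88 h, distance 1.63 km, net displacement 1.49 km
#>   average speed 1.86 km/h, straightness index 0.91
```

The ground-truth track's average speed is 2.03 km/h: the smoothed acoustic
track recovers the singer's speed to within a few percent (smoothing trades
a slight underestimate of fine-scale wiggle for robustness to localization
error), and its straightness index of 0.91 correctly identifies a
directional singer. `plot(sm)` draws the track.

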