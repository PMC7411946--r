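# barnloc

Grid-based indoor localization of dairy cows from the received signal
strength (RSS) of Bluetooth Low Energy (BLE) collar tags.

Commercial cow-tracking systems (UWB, WLAN) are accurate but expensive.
A much cheaper alternative attaches BLE tags to cow collars and lets a
handful of fixed receiving stations record the RSS of every 5 Hz
advertisement. The price is noise: tag orientation, animal bodies and
barn metalwork distort the signal by several dB, so the achievable
accuracy is metres, not centimetres — enough for behavioural monitoring
(time at the feed fence, queues at the milking robot, unusually long
walks), not for tracking individual steps. `barnloc` implements the full
decoding chain for such a system, plus a seeded synthetic barn simulator
so every stage can be tested without hardware.

## Method

* **Propagation model.** RSS relates to tag–station distance by the
  log-distance path-loss model `RSS = −10·n·log10(D) + A0`, fitted by
  OLS; the pooled open-space calibration `n = 0.84`, `A0 = −48.77 dB`
  is the system default.
* **Filtering.** Raw 5 Hz streams are smoothed per (tag, station) —
  centered moving mean (default, 10 s), median, or a constant-velocity
  Kalman filter — then folded into 5-s observation windows by
  per-station averaging.
* **Grid localization.** The barn is discretized into mapping points
  (~1 m). For each window, a squared-error surface compares measured RSS
  with a precomputed lookup table; measured and modelled values are first
  centered over the heard stations ("shifting factors"), cancelling
  per-tag/per-station level offsets.
* **Trajectory smoothing.** Windows are decoded jointly as a hidden
  Markov model: emission weights are reciprocal errors, and the
  transition matrix encodes the barn structure (weight `1/(1 + dist)`
  within 3 m, zero across obstacles, row-normalized). The Viterbi
  algorithm returns the maximum-a-posteriori path in the log domain.
* **Evaluation.** Event-level errors against reference locations, pooled
  and per-tag mean ± SD, cumulative error curves, occupancy maps and
  zone time distributions.
* **Simulator.** Markov-walk trajectories on the map (95% dwell) and RSS
  streams with the calibrated noise anatomy: 4 dB sample noise, 2.7 dB
  per-tag and 4.14 dB per-station offsets, 6 dB orientation dependence.

See `vignettes/barnloc-methods.Rmd` for the full model description,
parameter rationale and known limitations.

## Worked example

A densely covered 4 × 5 m waiting yard (0.5 m grid, 7 stations ~2 m
apart), 30 simulated minutes:

```r
library(barnloc)
yard <- prepare_barn_map(barn_map(
  extents = list(xmin = 0, xmax = 4, ymin = 0, ymax = 5),
  stations = data.frame(id = sprintf("Y%02d", 1:7),
                        x = c(0, 2, 4, 4, 4, 2, 0),
                        y = c(0, 0, 0, 2.5, 5, 5, 5), z = 3.5),
  resolution = 0.5, name = "waiting_yard"))

truth <- simulate_trajectory(yard, motion_spec(0.95), duration_s = 1800,
                             seed = 42)
rss   <- simulate_rss(truth, yard, noise = noise_spec(), seed = 43)
track <- localize(rss, yard)
accuracy_summary(localization_errors(track, make_reference(truth), yard))
#> <accuracy_summary> 23 events, 2.69 +/- 1.20 m pooled
#>   tag_id  n   mean_m     sd_m
#> 1    T01 23 2.686238 1.197249
```

The tag dwelt at 23 reference locations; the decoded track lands a mean
2.69 m from them (sample SD 1.20 m) — metre-scale accuracy, roughly half
the station spacing plus grid quantization, which is what this class of
system delivers in a well-covered area.

Fitting the propagation model from a simulated open-space calibration
(15 distances × 600 samples):

```r
rec <- simulate_open_space(default_propagation_model(), seed = 99)
fit_propagation_model(rec$distance_m, rec$rss_db)
#> <propagation_fit> n = 0.830 +/- 0.013, A0 = -48.82 +/- 0.11 dB, R^2 = 0.319
```

A packaged synthetic full-barn map (9.8 × 39 m, 10 stations, cubicles,
robot, waiting yard) ships at
`system.file("extdata", "synthetic_barn.yaml", package = "barnloc")` for
the occupancy / zone-monitoring application.

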