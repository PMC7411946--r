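# Synthetic telemetry: open-space propagation experiments, cow trajectories
# on the mapping-point grid, and noisy 5 Hz RSS streams.

#' RSS noise structure of the simulator
#'
#' Variance components of simulated RSS: i.i.d. per-advertisement gaussian
#' noise, a constant per-tag level offset, a constant per-station level
#' offset, a tag-orientation term with peak-to-peak range
#' `orientation_amp`, and an optional independent per-reception drop
#' probability.
#'
#' @param sample_noise_std Per-sample gaussian noise STD in dB (default 4,
#'   the near-gaussian barn regime).
#' @param per_tag_offset_std STD of the per-tag offsets in dB (default 2.7).
#' @param per_station_offset_std STD of the per-station offsets in dB
#'   (default 4.14).
#' @param orientation_amp Peak-to-peak orientation-dependent deviation in dB
#'   (default 6, the barn regime; about 17 in open space).
#' @param drop_prob Independent packet-drop probability per reception
#'   (default 0).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sample_noise_std = 4, per_tag_offset_std = 2.7,
                       per_station_offset_std = 4.14, orientation_amp = 6,
                       drop_prob = 0) {
  stopifnot(sample_noise_std >= 0, per_tag_offset_std >= 0,
            per_station_offset_std >= 0, orientation_amp >= 0,
            drop_prob >= 0, drop_prob < 1)
  structure(list(sample_noise_std = sample_noise_std,
                 per_tag_offset_std = per_tag_offset_std,
                 per_station_offset_std = per_station_offset_std,
                 orientation_amp = orientation_amp,
                 drop_prob = drop_prob),
            class = "noise_spec")
}

#' Noise-free simulator settings
#' @return A `noise_spec` with every component zero.
#' @export
zero_noise <- function() noise_spec(0, 0, 0, 0, 0)

#' Cow movement settings for the trajectory simulator
#'
#' @param dwell_fraction Probability of staying at the current mapping point
#'   over one window step (default 0.95: cows are stationary most of the
#'   time, walking takes under 5% of it).
#' @return A list of class `motion_spec`.
#' @export
motion_spec <- function(dwell_fraction = 0.95) {
  stopifnot(dwell_fraction >= 0, dwell_fraction <= 1)
  structure(list(dwell_fraction = dwell_fraction), class = "motion_spec")
}

#' Simulate the open-space propagation experiment
#'
#' Emulates the distance-calibration recordings: for every
#' tag x station x distance combination, `duration_s * rate_hz`
#' advertisements with RSS = model prediction + per-tag offset +
#' per-station offset + per-sample gaussian noise. Tag orientation is held
#' fixed by the experimental protocol, so no orientation term is applied.
#'
#' @param model A [propagation_model()].
#' @param distances Distances in metres (default 1:15).
#' @param duration_s Recording length per distance in seconds (default 120).
#' @param rate_hz Advertisement rate (default 5).
#' @param noise A [noise_spec()]; defaults to pure 4 dB sample noise.
#' @param n_tags,n_stations Number of tags / stations (default 1 each).
#' @param seed Optional RNG seed for reproducibility.
#' @return Data frame with columns `time`, `tag_id`, `station_id`,
#'   `distance_m`, `rss_db`.
#' @export
simulate_open_space <- function(model, distances = 1:15, duration_s = 120,
                                rate_hz = 5,
                                noise = noise_spec(per_tag_offset_std = 0,
                                                   per_station_offset_std = 0,
                                                   orientation_amp = 0),
                                n_tags = 1, n_stations = 1, seed = NULL) {
  stopifnot(inherits(model, "propagation_model"), inherits(noise, "noise_spec"),
            all(distances > 0), duration_s > 0, rate_hz > 0,
            n_tags >= 1, n_stations >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_per <- as.integer(round(duration_s * rate_hz))
  tags <- sprintf("T%02d", seq_len(n_tags))
  stns <- sprintf("S%02d", seq_len(n_stations))
  tag_off <- stats::rnorm(n_tags, 0, noise$per_tag_offset_std)
  stn_off <- stats::rnorm(n_stations, 0, noise$per_station_offset_std)
  g <- expand.grid(tag = seq_len(n_tags), stn = seq_len(n_stations),
                   d = distances, KEEP.OUT.ATTRS = FALSE)
  n_tot <- nrow(g) * n_per
  idx <- rep(seq_len(nrow(g)), each = n_per)
  rss <- predict_rss(model, g$d[idx]) + tag_off[g$tag[idx]] +
    stn_off[g$stn[idx]] +
    stats::rnorm(n_tot, 0, noise$sample_noise_std)
  data.frame(time = rep((seq_len(n_per) - 1L) / rate_hz, nrow(g)),
             tag_id = tags[g$tag[idx]],
             station_id = stns[g$stn[idx]],
             distance_m = g$d[idx],
             rss_db = rss,
             stringsAsFactors = FALSE)
}

#' Ground-truth movement chain of a barn map
#'
#' The Markov chain used to generate reference trajectories: stay
#' probability `dwell_fraction`; the remaining mass distributed over the
#' reachable neighbours (within `max_step` metres, passage clear of
#' obstacles) proportionally to `1 / (1 + dist)`.
#'
#' @param map A [barn_map()].
#' @param dwell_fraction Stay probability per window step (default 0.95).
#' @param max_step Maximum displacement per step in metres (default 3).
#' @return K x K row-stochastic matrix.
#' @export
movement_chain <- function(map, dwell_fraction = 0.95, max_step = 3) {
  stopifnot(inherits(map, "barn_map"))
  W <- build_transition_matrix(map$points, map$obstacles, max_step = max_step)
  diag(W) <- 0
  rs <- rowSums(W)
  G <- matrix(0, nrow(W), ncol(W))
  move <- rs > 0
  G[move, ] <- (1 - dwell_fraction) * W[move, , drop = FALSE] / rs[move]
  diag(G) <- ifelse(move, dwell_fraction, 1)
  G
}

#' Simulate a cow trajectory on the mapping-point grid
#'
#' Samples a Markov walk over the mapping points from [movement_chain()]:
#' the animal dwells at its current point with probability
#' `dwell_fraction` per step and otherwise moves to a reachable neighbour.
#' Position is constant within each step, so obstacles and the step-length
#' limit are respected by construction.
#'
#' @param map A [barn_map()].
#' @param motion A [motion_spec()].
#' @param duration_s Track length in seconds.
#' @param step_s Step (window) length in seconds (default 5).
#' @param tag_id Tag label (default `"T01"`).
#' @param start Starting point index (default: uniform random).
#' @param seed Optional RNG seed.
#' @return Data frame of class `reference_track`: `tag_id`, `t_start`,
#'   `point`; the step length is kept in attribute `"step_s"`.
#' @export
simulate_trajectory <- function(map, motion = motion_spec(), duration_s,
                                step_s = 5, tag_id = "T01", start = NULL,
                                seed = NULL) {
  stopifnot(inherits(map, "barn_map"), inherits(motion, "motion_spec"),
            duration_s > 0, step_s > 0, nrow(map$points) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  G <- movement_chain(map, motion$dwell_fraction)
  K <- nrow(G)
  n_steps <- as.integer(ceiling(duration_s / step_s))
  cum <- t(apply(G, 1L, cumsum))
  path <- integer(n_steps)
  path[1L] <- if (is.null(start)) sample.int(K, 1L) else as.integer(start)
  stopifnot(path[1L] >= 1L, path[1L] <= K)
  for (s in seq_len(n_steps - 1L)) {
    u <- stats::runif(1)
    path[s + 1L] <- min(findInterval(u, cum[path[s], ]) + 1L, K)
  }
  out <- data.frame(tag_id = tag_id,
                    t_start = (seq_len(n_steps) - 1L) * step_s,
                    point = path, stringsAsFactors = FALSE)
  attr(out, "step_s") <- step_s
  class(out) <- c("reference_track", "data.frame")
  out
}

#' Simulate the RSS streams of tracked tags
#'
#' Generates the raw 5 Hz advertisement receptions for every tag in a
#' reference track. Per reception:
#' RSS = model prediction at the 3-D tag--station distance
#' + per-tag offset + per-station offset
#' + (orientation_amp / 2) cos(heading - bearing to station)
#' + gaussian sample noise.
#' Offsets are drawn once per tag and once per station. The heading follows
#' the walking direction during a move and is redrawn uniformly at random
#' for each resting step. Receptions are then dropped independently with
#' probability `drop_prob`.
#'
#' @param track A `reference_track` (possibly several tags row-bound).
#' @param map A [barn_map()].
#' @param model A [propagation_model()].
#' @param noise A [noise_spec()].
#' @param rate_hz Advertisement rate (default 5).
#' @param seed Optional RNG seed.
#' @return RSS log data frame: `time`, `tag_id`, `station_id`, `rss_db`,
#'   sorted by time.
#' @export
simulate_rss <- function(track, map, model = default_propagation_model(),
                         noise = noise_spec(), rate_hz = 5, seed = NULL) {
  stopifnot(inherits(map, "barn_map"), inherits(model, "propagation_model"),
            inherits(noise, "noise_spec"), is.data.frame(track),
            all(c("tag_id", "t_start", "point") %in% names(track)),
            nrow(track) >= 1L, rate_hz > 0)
  if (!is.null(seed)) set.seed(seed)
  step_s <- attr(track, "step_s")
  if (is.null(step_s)) {
    dts <- diff(sort(unique(track$t_start)))
    step_s <- if (length(dts)) min(dts) else 5
  }
  per_step <- as.integer(round(step_s * rate_hz))
  tags <- unique(track$tag_id)
  stns <- map$stations
  S <- nrow(stns)
  tag_off <- stats::rnorm(length(tags), 0, noise$per_tag_offset_std)
  names(tag_off) <- tags
  stn_off <- stats::rnorm(S, 0, noise$per_station_offset_std)
  out <- vector("list", length(tags))
  for (ti in seq_along(tags)) {
    tr <- track[track$tag_id == tags[ti], , drop = FALSE]
    tr <- tr[order(tr$t_start), , drop = FALSE]
    px <- map$points$x[tr$point]
    py <- map$points$y[tr$point]
    moved <- c(FALSE, diff(px) != 0 | diff(py) != 0)
    heading <- stats::runif(nrow(tr), 0, 2 * pi)
    if (any(moved))
      heading[moved] <- atan2(diff(py), diff(px))[moved[-1L]]
    tick_step <- rep(seq_len(nrow(tr)), each = per_step)
    tick_t <- rep(tr$t_start, each = per_step) +
      rep((seq_len(per_step) - 1L) / rate_hz, nrow(tr))
    n_ticks <- length(tick_t)
    tx <- px[tick_step]; ty <- py[tick_step]; th <- heading[tick_step]
    dx <- outer(tx, stns$x, "-")
    dy <- outer(ty, stns$y, "-")
    dz <- matrix(map$tag_height - stns$z, n_ticks, S, byrow = TRUE)
    d <- pmax(sqrt(dx^2 + dy^2 + dz^2), 0.1)
    bearing <- atan2(-dy, -dx)         # from tag towards station
    rss <- predict_rss(model, as.numeric(d)) +
      tag_off[ti] +
      rep(stn_off, each = n_ticks) +
      (noise$orientation_amp / 2) * cos(th - as.numeric(bearing)) +
      stats::rnorm(n_ticks * S, 0, noise$sample_noise_std)
    rec <- data.frame(time = rep(tick_t, S),
                      tag_id = tags[ti],
                      station_id = rep(stns$id, each = n_ticks),
                      rss_db = rss, stringsAsFactors = FALSE)
    if (noise$drop_prob > 0)
      rec <- rec[stats::runif(nrow(rec)) >= noise$drop_prob, , drop = FALSE]
    out[[ti]] <- rec
  }
  out <- do.call(rbind, out)
  out <- out[order(out$time, out$tag_id, out$station_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference dwell events from a trajectory
#'
#' Converts a reference track into evaluation events: maximal runs at one
#' mapping point lasting at least `min_dwell_s` seconds (shorter visits are
#' not registered).
#'
#' @param track A `reference_track`.
#' @param min_dwell_s Minimum dwell duration in seconds (default 5).
#' @return Data frame with columns `tag_id`, `t_start`, `t_end`, `point`.
#' @export
make_reference <- function(track, min_dwell_s = 5) {
  stopifnot(is.data.frame(track),
            all(c("tag_id", "t_start", "point") %in% names(track)))
  step_s <- attr(track, "step_s")
  out <- list()
  for (tg in unique(track$tag_id)) {
    tr <- track[track$tag_id == tg, , drop = FALSE]
    tr <- tr[order(tr$t_start), , drop = FALSE]
    st <- if (is.null(step_s)) {
      dts <- diff(tr$t_start)
      if (length(dts)) min(dts) else 5
    } else step_s
    r <- rle(tr$point)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- data.frame(tag_id = tg,
                     t_start = tr$t_start[starts],
                     t_end = tr$t_start[ends] + st,
                     point = r$values, stringsAsFactors = FALSE)
    out[[tg]] <- ev[ev$t_end - ev$t_start >= min_dwell_s, , drop = FALSE]
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}
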