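test_that("open-space recordings hold 600 samples per distance", {
  m <- default_propagation_model()
  rec <- simulate_open_space(m, distances = c(1, 5, 10), seed = 51)
  cnt <- table(rec$distance_m)
  expect_equal(as.numeric(cnt), rep(600, 3))   # 120 s at 5 Hz
})

test_that("noise-free open-space samples equal the model prediction", {
  m <- default_propagation_model()
  rec <- simulate_open_space(m, distances = c(2, 8), noise = zero_noise())
  expect_equal(rec$rss_db, predict_rss(m, rec$distance_m))
})

test_that("open-space simulation is reproducible under a fixed seed", {
  m <- default_propagation_model()
  a <- simulate_open_space(m, distances = 1:3, duration_s = 5, seed = 52)
  b <- simulate_open_space(m, distances = 1:3, duration_s = 5, seed = 52)
  expect_identical(a, b)
  c <- simulate_open_space(m, distances = 1:3, duration_s = 5, seed = 53)
  expect_false(identical(a$rss_db, c$rss_db))
})

test_that("dwell fraction one keeps the trajectory stationary", {
  map <- arena_map()
  tr <- simulate_trajectory(map, motion_spec(1), 600, seed = 54)
  expect_equal(length(unique(tr$point)), 1L)
  expect_equal(nrow(tr), 120L)
})

test_that("trajectories respect obstacles and the step limit", {
  wall <- matrix(c(2, 2, -1, 9), 2, 2)
  map <- arena_map(4, 8, 1, obstacles = list(wall))
  tr <- simulate_trajectory(map, motion_spec(0.5), 3000, seed = 55)
  x <- map$points$x[tr$point]; y <- map$points$y[tr$point]
  moved <- which(diff(tr$point) != 0)
  for (i in moved) {
    expect_true(passage_clear(c(x[i], y[i]), c(x[i + 1], y[i + 1]),
                              map$obstacles))
  }
  expect_true(all(sqrt(diff(x)^2 + diff(y)^2) <= 3 + 1e-9))
})

test_that("long-run occupancy approaches the chain's stationary law", {
  map <- arena_map(2, 2, 1)          # 9 points, fast mixing
  G <- movement_chain(map, dwell_fraction = 0.5)
  expect_equal(rowSums(G), rep(1, 9), tolerance = 1e-12)
  ev <- eigen(t(G))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  tr <- simulate_trajectory(map, motion_spec(0.5), 5 * 60000, seed = 56)
  occ <- tabulate(tr$point, 9) / nrow(tr)
  expect_lt(max(abs(occ - stat)), 1e-2)
})

test_that("noise-free RSS for a static tag equals its lookup row", {
  map <- prepare_barn_map(arena_map())
  tr <- simulate_trajectory(map, motion_spec(1), 60, start = 5, seed = 57)
  rss <- simulate_rss(tr, map, noise = zero_noise())
  for (sid in map$stations$id) {
    expect_equal(unique(rss$rss_db[rss$station_id == sid]),
                 unname(map$rss_map[5, sid]))
  }
  expect_equal(nrow(rss), 60 * 5 * 4)   # ticks x stations
})

test_that("orientation sweep spans the configured amplitude", {
  # single station due east: cos term sweeps +/- amp/2 with heading
  map <- prepare_barn_map(arena_map(
    stations = data.frame(id = "E", x = 4, y = 2, z = 1.5)))
  k <- which(map$points$x == 0 & map$points$y == 2)
  tr <- data.frame(tag_id = "T01", t_start = (0:199) * 5, point = k)
  attr(tr, "step_s") <- 5
  class(tr) <- c("reference_track", "data.frame")
  rss <- simulate_rss(tr, map,
                      noise = noise_spec(0, 0, 0, orientation_amp = 6),
                      seed = 58)
  dev <- rss$rss_db - map$rss_map[k, "E"]
  expect_equal(max(dev) - min(dev), 6, tolerance = 0.1)
})

test_that("station offset variability is recovered through the pipeline", {
  st <- data.frame(id = sprintf("S%02d", 1:20),
                   x = runif(20, 0, 4) * 0 + rep(c(0, 4), 10),
                   y = rep(seq(0, 4.5, 0.5), each = 2), z = 3)
  map <- prepare_barn_map(arena_map(stations = st))
  tr <- simulate_trajectory(map, motion_spec(1), 120, start = 12, seed = 59)
  rec <- simulate_rss(tr, map,
                      noise = noise_spec(sample_noise_std = 1,
                                         per_tag_offset_std = 0,
                                         per_station_offset_std = 4.14,
                                         orientation_amp = 0),
                      seed = 60)
  # remove the geometry, leaving offsets + sample noise
  pred <- map$rss_map[12, rec$station_id]
  resid <- tapply(rec$rss_db - pred, rec$station_id, mean)
  expect_equal(sd(resid), 4.14, tolerance = 1.6)
})

test_that("reference events require a five-second dwell", {
  tr <- data.frame(tag_id = "T01", t_start = (0:11) * 5,
                   point = c(1, 1, 1, 2, 1, 1, 3, 3, 3, 3, 4, 4))
  attr(tr, "step_s") <- 5
  ev <- make_reference(tr, min_dwell_s = 10)
  # the single-window visits to 2 fall below the dwell threshold
  expect_equal(ev$point, c(1, 1, 3, 4))
  expect_equal(ev$t_start, c(0, 20, 30, 50))
  expect_equal(ev$t_end, c(15, 30, 50, 60))
  # a stationary track yields one spanning event
  tr2 <- data.frame(tag_id = "T01", t_start = (0:9) * 5, point = 7)
  attr(tr2, "step_s") <- 5
  ev2 <- make_reference(tr2)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$t_end - ev2$t_start, 50)
})

test_that("packet drops thin the stream at the configured rate", {
  map <- prepare_barn_map(arena_map())
  tr <- simulate_trajectory(map, motion_spec(1), 600, seed = 61)
  rss <- simulate_rss(tr, map, noise = noise_spec(drop_prob = 0.3),
                      seed = 62)
  expect_equal(nrow(rss) / (600 * 5 * 4), 0.7, tolerance = 0.02)
})
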