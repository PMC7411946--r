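prep_arena <- function(...) prepare_barn_map(arena_map(...))

test_that("error surface vanishes at a perfectly matching point", {
  map <- prep_arena()
  k <- 7L
  m <- map$rss_map[k, ]
  for (sh in c(TRUE, FALSE)) {
    s <- error_surface(m, map, shifted = sh)
    expect_equal(s$err[k], 0)
    expect_equal(best_point(s), k)
    expect_true(all(s$err >= 0))
  }
})

test_that("a constant offset is cancelled by the shifted error only", {
  map <- prep_arena()
  k <- 12L
  m <- map$rss_map[k, ] + 5
  s_shift <- error_surface(m, map, shifted = TRUE)
  s_raw <- error_surface(m, map, shifted = FALSE)
  expect_equal(s_shift$err[k], 0, tolerance = 1e-12)
  expect_equal(s_raw$err[k], length(m) * 25)   # |heard| * c^2
})

test_that("error surfaces match the hand-expanded definition", {
  map <- prep_arena()
  set.seed(31)
  for (i in 1:20) {
    heard <- sample(map$stations$id, sample(3:4, 1))
    m <- setNames(rnorm(length(heard), -60, 6), heard)
    for (sh in c(TRUE, FALSE)) {
      s <- error_surface(m, map, shifted = sh)
      expect_equal(s$err, naive_error_surface(m, map$rss_map, sh),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("windows heard by too few stations are flagged unlocatable", {
  map <- prep_arena()
  m <- map$rss_map[3, 1:2]
  expect_warning(s <- error_surface(m, map), "unlocatable")
  expect_null(s)
})

test_that("best point breaks ties at the lowest index", {
  expect_equal(best_point(c(3, 1, 2)), 2L)
  expect_equal(best_point(c(2, 2, 2)), 1L)
})

test_that("emission probabilities are reciprocal errors, normalized", {
  expect_equal(emission_probabilities(c(1, 2, 4)), c(4, 2, 1) / 7)
  expect_equal(emission_probabilities(rep(3, 5)), rep(0.2, 5))
  p <- emission_probabilities(c(0, 1, 1))
  expect_gt(p[1], 0.999)          # a zero error takes almost all mass
  expect_equal(sum(p), 1)
  set.seed(32)
  for (i in 1:10)
    expect_equal(sum(emission_probabilities(runif(20, 0, 50))), 1)
})

test_that("single-window decoding maximizes prior times emission", {
  tm <- matrix(0.25, 4, 4)
  em <- matrix(c(0.1, 0.5, 0.2, 0.2), 1)
  expect_equal(viterbi_decode(em, tm), 2L)
  prior <- c(0.9, 0.02, 0.04, 0.04)
  expect_equal(viterbi_decode(em, tm, prior), 1L)
})

test_that("uniform emissions leave the path at the strongest stay point", {
  map <- prep_arena()
  K <- nrow(map$points)
  em <- matrix(1 / K, 6, K)
  path <- viterbi_decode(em, map$tm)
  expect_equal(length(unique(path)), 1L)
  expect_equal(path[1], which.max(diag(map$tm)))
})

test_that("viterbi equals exhaustive path enumeration on random instances", {
  set.seed(33)
  for (i in 1:25) {
    K <- sample(2:5, 1); TT <- sample(2:5, 1)
    tm <- matrix(runif(K * K), K); tm <- tm / rowSums(tm)
    em <- matrix(runif(TT * K), TT); em <- em / rowSums(em)
    expect_equal(viterbi_decode(em, tm), brute_force_viterbi(em, tm))
  }
})

test_that("all-zero emission rows are bridged by the transition prior", {
  tm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  em <- rbind(c(1, 0), c(0, 0), c(1, 0))
  expect_equal(viterbi_decode(em, tm), c(1L, 1L, 1L))
})

test_that("localize is deterministic and splits interleaved tags", {
  map <- prep_arena()
  tr1 <- simulate_trajectory(map, motion_spec(0.9), 300, tag_id = "T01",
                             seed = 34)
  tr2 <- simulate_trajectory(map, motion_spec(0.9), 300, tag_id = "T02",
                             seed = 35)
  both <- rbind(tr1, tr2)
  attr(both, "step_s") <- 5
  rss <- simulate_rss(both, map, noise = noise_spec(sample_noise_std = 2),
                      seed = 36)
  trk <- localize(rss, map)
  expect_identical(localize(rss, map), trk)
  expect_setequal(unique(trk$tag_id), c("T01", "T02"))
  # each tag decoded independently of the other's records
  solo <- localize(rss[rss$tag_id == "T01", ], map)
  expect_equal(trk$point[trk$tag_id == "T01"], solo$point)
})

test_that("decoded windows at a noise-free stationary tag recover its point", {
  map <- prep_arena()
  tr <- simulate_trajectory(map, motion_spec(1), 120, start = 9, seed = 37)
  rss <- simulate_rss(tr, map, noise = zero_noise())
  trk <- localize(rss, map, filter = "none")
  expect_equal(trk$point, rep(9L, 24))
})

test_that("unsmoothed decoding returns per-window best points", {
  map <- prep_arena()
  tr <- simulate_trajectory(map, motion_spec(0.9), 300, seed = 42)
  rss <- simulate_rss(tr, map, noise = noise_spec(sample_noise_std = 2),
                      seed = 43)
  raw <- localize(rss, map, smooth = FALSE)
  wins <- fold_windows(filter_rss(rss, "mean"), 5)
  for (i in seq_len(nrow(raw))) {
    w <- wins[wins$t_start == raw$t_start[i], ]
    s <- error_surface(setNames(w$rss_db, w$station_id), map)
    expect_equal(raw$point[i], best_point(s))
  }
})

test_that("shifting every station by a constant leaves the track unchanged", {
  map <- prep_arena()
  tr <- simulate_trajectory(map, motion_spec(0.9), 300, seed = 38)
  rss <- simulate_rss(tr, map, noise = noise_spec(), seed = 39)
  rss2 <- rss
  rss2$rss_db <- rss2$rss_db + 12.5
  expect_equal(localize(rss, map)$point, localize(rss2, map)$point)
})

test_that("decoded tracks never traverse forbidden transitions", {
  map <- prep_arena(6, 8, 1,
                    obstacles = list(matrix(c(3, 3, -1, 6), 2, 2)))
  tr <- simulate_trajectory(map, motion_spec(0.8), 600, seed = 40)
  rss <- simulate_rss(tr, map, noise = noise_spec(), seed = 41)
  trk <- localize(rss, map)
  steps <- cbind(trk$point[-nrow(trk)], trk$point[-1])
  expect_true(all(map$tm[steps] > 0))
  d <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  expect_true(all(d <= 3 + 1e-9))
})
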