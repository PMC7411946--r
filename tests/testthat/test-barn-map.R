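test_that("grid covers the extents at the requested resolution", {
  g <- build_grid(list(xmin = 0, xmax = 4, ymin = 0, ymax = 5), 1)
  expect_equal(nrow(g), 30L)          # 5 x 6 boundary-inclusive points
  expect_equal(g$point, seq_len(30L))
  # row-major: x varies fastest
  expect_equal(g$x[1:5], 0:4)
  expect_equal(g$y[1:5], rep(0, 5))
  g2 <- build_grid(list(xmin = 0, xmax = 4, ymin = 0, ymax = 5), 0.5)
  expect_equal(nrow(g2), 9L * 11L)
  expect_error(build_grid(list(xmin = 0, xmax = 4, ymin = 0, ymax = 5), 10),
               "extents")
  expect_error(build_grid(list(xmin = 0, xmax = 4, ymin = 0, ymax = 5), -1),
               "positive")
})

test_that("closed obstacle polygons carve points out of the grid", {
  box <- list(c(-1, -1), c(3, -1), c(3, 3), c(-1, 3), c(-1, -1))
  g <- build_grid(list(xmin = 0, xmax = 2, ymin = 0, ymax = 2), 1,
                  obstacles = list(box))
  expect_equal(nrow(g), 0L)
  inner <- list(c(0.5, 0.5), c(1.5, 0.5), c(1.5, 1.5), c(0.5, 1.5),
                c(0.5, 0.5))
  g2 <- build_grid(list(xmin = 0, xmax = 2, ymin = 0, ymax = 2), 1,
                   obstacles = list(inner))
  expect_equal(nrow(g2), 8L)          # 9 points minus the centre
  expect_false(any(g2$x == 1 & g2$y == 1))
})

test_that("grid generation is deterministic", {
  ex <- list(xmin = 0, xmax = 9.8, ymin = 3, ymax = 42)
  expect_identical(build_grid(ex, 1), build_grid(ex, 1))
})

test_that("passages are blocked by intersecting or touching obstacles", {
  wall <- list(matrix(c(1, 1, -1, 1), 2, 2))   # vertical segment x = 1
  expect_true(passage_clear(c(0, 0), c(2, 5)))
  expect_false(passage_clear(c(0, 0), c(2, 0), wall))
  expect_true(passage_clear(c(0, 2), c(2, 2), wall))
  # obstacle touching exactly one endpoint blocks (conservative convention)
  expect_false(passage_clear(c(1, 1), c(3, 1), wall))
  expect_false(passage_clear(c(0, 1), c(1, 1), wall))
})

test_that("lookup table holds model RSS at 3-D distances", {
  m <- propagation_model(0.84, -48.77)
  pts <- data.frame(point = 1:2, x = c(1, 0), y = c(0, 0))
  st <- data.frame(id = c("A", "B"),
                   x = c(0, 0), y = c(0, 0), z = c(1.5, 4.5))
  lut <- build_rss_lookup(pts, st, m, tag_height = 1.5)
  expect_equal(unname(lut[1, "A"]), -48.77)              # exactly 1 m
  expect_equal(unname(lut[2, "B"]),
               -10 * 0.84 * log10(3) - 48.77)            # 3 m vertical
  # symmetric stations give equal entries
  st2 <- data.frame(id = c("L", "R"), x = c(-2, 4), y = 0, z = 3)
  lut2 <- build_rss_lookup(pts[1, ], st2, m)
  expect_equal(unname(lut2[1, "L"]), unname(lut2[1, "R"]))
  # coincident station-point distance is clamped, not singular
  expect_true(is.finite(build_rss_lookup(pts, st, m, tag_height = 1.5)[2, "A"]))
})

test_that("lookup decays along a ray leaving a station", {
  m <- default_propagation_model()
  pts <- data.frame(point = 1:10, x = 1:10, y = 0)
  st <- data.frame(id = "A", x = 0, y = 0, z = 1.5)
  expect_true(all(diff(build_rss_lookup(pts, st, m)[, 1]) < 0))
})

test_that("transition matrix follows the stay/distance/obstacle rules", {
  # two points 1 m apart: unnormalized [1, 1/2] -> rows [2/3, 1/3]
  pts <- data.frame(point = 1:2, x = c(0, 1), y = 0)
  tm <- build_transition_matrix(pts)
  expect_equal(tm, matrix(c(2/3, 1/3, 1/3, 2/3), 2, 2, byrow = TRUE))
  # beyond 3 m: disconnected
  far <- data.frame(point = 1:2, x = c(0, 4), y = 0)
  expect_equal(build_transition_matrix(far), diag(2))
  # exactly 3 m is still reachable
  edge <- data.frame(point = 1:2, x = c(0, 3), y = 0)
  expect_true(build_transition_matrix(edge)[1, 2] > 0)
  # a wall between the points disconnects them
  wall <- list(matrix(c(0.5, 0.5, -1, 1), 2, 2))
  expect_equal(build_transition_matrix(pts, wall), diag(2))
})

test_that("transition matrix is row-stochastic with symmetric zero pattern", {
  map <- arena_map(6, 8, 1, obstacles = list(matrix(c(2, 2, 1, 6), 2, 2)))
  tm <- build_transition_matrix(map$points, map$obstacles)
  expect_equal(rowSums(tm), rep(1, nrow(tm)), tolerance = 1e-9)
  expect_true(all((tm == 0) == t(tm == 0)))
  expect_true(all(tm >= 0))
})

test_that("barn_map validates stations and labels zones", {
  st <- data.frame(id = "A", x = 50, y = 1, z = 3)
  expect_error(arena_map(stations = st), "outside")
  st2 <- data.frame(id = "A", x = 1, y = 1, z = -3)
  expect_error(arena_map(stations = st2), "outside|z")
  zones <- list(south = list(c(-1, -1), c(5, -1), c(5, 2.5), c(-1, 2.5),
                             c(-1, -1)))
  map <- arena_map(zones = zones)
  expect_setequal(unique(map$points$zone), c("south", "unassigned"))
  expect_true(all(map$points$zone[map$points$y <= 2] == "south"))
})
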