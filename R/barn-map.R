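# Barn geometry: mapping-point grid, RSS lookup table, transition matrix.

.cross2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

.on_segment <- function(px, py, qx, qy, rx, ry, tol) {
  # r collinear with pq assumed; is r within the bounding box of pq?
  rx >= min(px, qx) - tol && rx <= max(px, qx) + tol &&
    ry >= min(py, qy) - tol && ry <= max(py, qy) + tol
}

#' Do two 2-D segments intersect?
#'
#' Closed-segment intersection test: touching at an endpoint or collinear
#' overlap counts as intersecting. Used with the conservative convention
#' that a passage touching an obstacle is blocked.
#'
#' @param p1,p2 Numeric length-2 endpoints of the first segment.
#' @param q1,q2 Numeric length-2 endpoints of the second segment.
#' @param tol Absolute tolerance for collinearity tests.
#' @return Logical scalar.
#' @keywords internal
segments_intersect <- function(p1, p2, q1, q2, tol = 1e-9) {
  d1 <- .cross2(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- .cross2(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- .cross2(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- .cross2(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol)))
    return(TRUE)
  if (abs(d1) <= tol &&
      .on_segment(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2], tol)) return(TRUE)
  if (abs(d2) <= tol &&
      .on_segment(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2], tol)) return(TRUE)
  if (abs(d3) <= tol &&
      .on_segment(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2], tol)) return(TRUE)
  if (abs(d4) <= tol &&
      .on_segment(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2], tol)) return(TRUE)
  FALSE
}

# even-odd point-in-polygon; poly is an n x 2 matrix (open or closed ring)
.point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (n >= 2L && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) return(rep(FALSE, length(px)))
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

.as_obstacle <- function(o) {
  m <- if (is.matrix(o)) o else do.call(rbind, lapply(o, as.numeric))
  storage.mode(m) <- "double"
  if (ncol(m) != 2L || nrow(m) < 2L)
    stop("an obstacle must be a polyline of at least two (x, y) vertices",
         call. = FALSE)
  m
}

.is_closed <- function(m) nrow(m) >= 4L && all(m[1, ] == m[nrow(m), ])

#' Build the mapping-point grid
#'
#' Lays a regular grid of localization mapping points over the barn extents
#' at the given resolution (boundary points included), excluding points that
#' fall strictly inside closed obstacle polygons. Indices are assigned
#' row-major: y rows from low to high, x varying fastest.
#'
#' @param extents List or vector with `xmin`, `xmax`, `ymin`, `ymax` in
#'   metres.
#' @param resolution Grid spacing in metres (> 0, not larger than either
#'   extent span).
#' @param obstacles List of obstacle polylines (n x 2 matrices or lists of
#'   (x, y) pairs); only closed rings exclude grid points.
#' @return Data frame with columns `point` (1-based index), `x`, `y`.
#' @export
build_grid <- function(extents, resolution, obstacles = list()) {
  ex <- as.list(extents)
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax") %in% names(ex)))
  if (!is.numeric(resolution) || resolution <= 0)
    stop("`resolution` must be positive", call. = FALSE)
  if (resolution > (ex$xmax - ex$xmin) || resolution > (ex$ymax - ex$ymin))
    stop("`resolution` is larger than the barn extents", call. = FALSE)
  xs <- seq(ex$xmin, ex$xmax + 1e-9, by = resolution)
  ys <- seq(ex$ymin, ex$ymax + 1e-9, by = resolution)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  keep <- rep(TRUE, nrow(g))
  for (o in obstacles) {
    m <- .as_obstacle(o)
    if (.is_closed(m))
      keep <- keep & !.point_in_polygon(g$x, g$y, m)
  }
  g <- g[keep, , drop = FALSE]
  rownames(g) <- NULL
  data.frame(point = seq_len(nrow(g)), x = g$x, y = g$y)
}

#' Is the straight passage between two points clear of obstacles?
#'
#' @param p,q Numeric length-2 floor-plane coordinates (metres).
#' @param obstacles List of obstacle polylines (n x 2 matrices).
#' @return `TRUE` iff the closed segment from `p` to `q` intersects no
#'   obstacle segment; touching an obstacle (including at an endpoint)
#'   counts as blocked.
#' @export
passage_clear <- function(p, q, obstacles = list()) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 2L, length(q) == 2L)
  for (o in obstacles) {
    m <- .as_obstacle(o)
    for (s in seq_len(nrow(m) - 1L)) {
      if (segments_intersect(p, q, m[s, ], m[s + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Precompute the RSS lookup table
#'
#' Model RSS at every mapping point for every station, using the 3-D
#' Euclidean distance between the station antenna and the tag held at
#' `tag_height` above the point. Distances below 0.1 m are clamped to
#' 0.1 m to avoid the logarithmic singularity.
#'
#' @param points Mapping-point data frame from [build_grid()].
#' @param stations Data frame with columns `id`, `x`, `y`, `z` (metres).
#' @param model A [propagation_model()].
#' @param tag_height Collar tag height above the floor in metres
#'   (default 1.5).
#' @return K x S numeric matrix of model RSS (dB) with station ids as
#'   column names.
#' @export
build_rss_lookup <- function(points, stations, model, tag_height = 1.5) {
  stopifnot(inherits(model, "propagation_model"),
            is.data.frame(points), nrow(points) >= 1L,
            is.data.frame(stations), nrow(stations) >= 1L,
            all(c("id", "x", "y", "z") %in% names(stations)))
  dx <- outer(points$x, stations$x, "-")
  dy <- outer(points$y, stations$y, "-")
  dz <- matrix(tag_height - stations$z, nrow(points), nrow(stations),
               byrow = TRUE)
  d <- pmax(sqrt(dx^2 + dy^2 + dz^2), 0.1)
  out <- predict_rss(model, as.numeric(d))
  dim(out) <- dim(d)
  colnames(out) <- as.character(stations$id)
  out
}

#' Build the barn-structure transition matrix
#'
#' Row-stochastic movement probabilities between mapping points over one
#' observation window. Unnormalized weights: 1 on the diagonal (staying);
#' 0 between points farther apart than `max_step` or separated by an
#' obstacle; `1 / (1 + dist(i, j))` otherwise. Each row is then normalized
#' to sum to one.
#'
#' @param points Mapping-point data frame from [build_grid()].
#' @param obstacles List of obstacle polylines.
#' @param max_step Maximum per-window displacement in metres (default 3).
#' @return K x K row-stochastic matrix.
#' @export
build_transition_matrix <- function(points, obstacles = list(), max_step = 3) {
  stopifnot(is.data.frame(points), nrow(points) >= 1L, max_step > 0)
  K <- nrow(points)
  D <- unname(as.matrix(stats::dist(cbind(points$x, points$y))))
  W <- 1 / (1 + D)
  W[D > max_step] <- 0
  diag(W) <- 1
  if (length(obstacles) > 0L) {
    cand <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (!passage_clear(c(points$x[i], points$y[i]),
                         c(points$x[j], points$y[j]), obstacles)) {
        W[i, j] <- 0
        W[j, i] <- 0
      }
    }
  }
  W / rowSums(W)
}

#' Assemble a barn map
#'
#' Builds the container tying together barn extents, stations, obstacles,
#' named zones and the mapping-point grid. The RSS lookup table and the
#' transition matrix are attached by [prepare_barn_map()].
#'
#' @param extents List with `xmin`, `xmax`, `ymin`, `ymax` (metres).
#' @param stations Data frame with columns `id`, `x`, `y`, `z`; stations
#'   must lie within the floor extents with `z > 0`.
#' @param obstacles List of obstacle polylines (n x 2 matrices or lists of
#'   (x, y) pairs). Closed rings also exclude interior grid points.
#' @param zones Named list of closed polygons labelling barn areas
#'   (e.g. feeding, cubicles, waiting_yard, robot); points outside every
#'   zone get the label `"unassigned"`.
#' @param resolution Mapping-point grid spacing in metres (default 1).
#' @param tag_height Tag height in metres (default 1.5).
#' @param name Map label.
#' @return An object of class `barn_map`.
#' @export
barn_map <- function(extents, stations, obstacles = list(), zones = list(),
                     resolution = 1, tag_height = 1.5, name = "barn") {
  ex <- as.list(extents)[c("xmin", "xmax", "ymin", "ymax")]
  stopifnot(!anyNA(match(c("xmin", "xmax", "ymin", "ymax"), names(ex))),
            ex$xmax > ex$xmin, ex$ymax > ex$ymin,
            is.data.frame(stations),
            all(c("id", "x", "y", "z") %in% names(stations)))
  stations <- data.frame(id = as.character(stations$id),
                         x = as.numeric(stations$x),
                         y = as.numeric(stations$y),
                         z = as.numeric(stations$z),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(stations$id))
    stop("duplicate station ids", call. = FALSE)
  bad <- stations$x < ex$xmin | stations$x > ex$xmax |
    stations$y < ex$ymin | stations$y > ex$ymax | stations$z <= 0
  if (any(bad))
    stop(sprintf("station(s) outside barn extents or at z <= 0: %s",
                 paste(stations$id[bad], collapse = ", ")), call. = FALSE)
  obstacles <- lapply(obstacles, .as_obstacle)
  zones <- lapply(zones, .as_obstacle)
  points <- build_grid(ex, resolution, obstacles)
  zone <- rep("unassigned", nrow(points))
  for (zn in names(zones)) {
    hit <- .point_in_polygon(points$x, points$y, zones[[zn]])
    zone[hit & zone == "unassigned"] <- zn
  }
  points$zone <- zone
  structure(list(name = name, extents = ex, resolution = resolution,
                 tag_height = tag_height, stations = stations,
                 obstacles = obstacles, zones = zones, points = points,
                 model = NULL, rss_map = NULL, tm = NULL),
            class = "barn_map")
}

#' Attach the RSS lookup table and transition matrix to a map
#'
#' @param map A [barn_map()].
#' @param model A [propagation_model()]; defaults to the pooled system
#'   model.
#' @param max_step Maximum per-window displacement in metres (default 3).
#' @return The map with `model`, `rss_map` and `tm` filled in.
#' @export
prepare_barn_map <- function(map, model = default_propagation_model(),
                             max_step = 3) {
  stopifnot(inherits(map, "barn_map"))
  map$model <- model
  map$rss_map <- build_rss_lookup(map$points, map$stations, model,
                                  tag_height = map$tag_height)
  map$tm <- build_transition_matrix(map$points, map$obstacles,
                                    max_step = max_step)
  map
}

#' @export
print.barn_map <- function(x, ...) {
  cat(sprintf(
    "<barn_map> '%s': %.1f x %.1f m, %d mapping points @ %.2g m, %d stations, %d obstacles%s\n",
    x$name, x$extents$xmax - x$extents$xmin, x$extents$ymax - x$extents$ymin,
    nrow(x$points), x$resolution, nrow(x$stations), length(x$obstacles),
    if (is.null(x$rss_map)) " (lookup not prepared)" else ""))
  invisible(x)
}
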