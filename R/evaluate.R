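# Accuracy metrics against reference locations; occupancy and zone maps.

#' Localization error per reference event
#'
#' For every reference event the decoded mapping point is the one occupying
#' the majority of the track windows whose start falls inside the event
#' interval (count ties broken by the lowest point index); the event error
#' is the Euclidean floor-plane distance between that point and the
#' reference location. Events without any decoded window are skipped with a
#' warning.
#'
#' @param track A `cow_track` from [localize()].
#' @param refs Reference events: data frame with `tag_id`, `t_start`,
#'   `t_end` and either `point` (mapping-point index) or `x`, `y`
#'   coordinates.
#' @param map The [barn_map()] the track was decoded on.
#' @return Data frame with one row per matched event: `tag_id`, `t_start`,
#'   `t_end`, `est_point`, `ref_x`, `ref_y`, `error_m`.
#' @export
localization_errors <- function(track, refs, map) {
  stopifnot(is.data.frame(track), is.data.frame(refs),
            inherits(map, "barn_map"),
            all(c("tag_id", "t_start", "point") %in% names(track)),
            all(c("tag_id", "t_start", "t_end") %in% names(refs)))
  has_point <- "point" %in% names(refs)
  if (!has_point && !all(c("x", "y") %in% names(refs)))
    stop("`refs` needs a `point` column or `x`/`y` columns", call. = FALSE)
  out <- vector("list", nrow(refs))
  skipped <- 0L
  for (i in seq_len(nrow(refs))) {
    ev <- refs[i, ]
    sel <- track$tag_id == ev$tag_id &
      track$t_start >= ev$t_start & track$t_start < ev$t_end
    if (!any(sel)) {
      skipped <- skipped + 1L
      next
    }
    pts <- track$point[sel]
    tab <- table(pts)
    cand <- as.integer(names(tab)[tab == max(tab)])
    est <- min(cand)
    rx <- if (has_point) map$points$x[ev$point] else ev$x
    ry <- if (has_point) map$points$y[ev$point] else ev$y
    out[[i]] <- data.frame(
      tag_id = ev$tag_id, t_start = ev$t_start, t_end = ev$t_end,
      est_point = est, ref_x = rx, ref_y = ry,
      error_m = sqrt((map$points$x[est] - rx)^2 + (map$points$y[est] - ry)^2),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(sprintf("%d reference event(s) had no decoded windows and were skipped",
                    skipped), call. = FALSE)
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(tag_id = character(0), t_start = numeric(0),
                      t_end = numeric(0), est_point = integer(0),
                      ref_x = numeric(0), ref_y = numeric(0),
                      error_m = numeric(0))
  rownames(res) <- NULL
  res
}

#' Summarize localization accuracy
#'
#' Per-tag and pooled mean +/- STD of the event errors (sample SD, n - 1
#' denominator) and the empirical cumulative error curve (fraction of
#' events with error not exceeding each observed value).
#'
#' @param errors Output of [localization_errors()], or a bare numeric error
#'   vector (treated as a single tag `"all"`).
#' @return A list of class `accuracy_summary`: `per_tag` (data frame with
#'   `tag_id`, `n`, `mean_m`, `sd_m`), `pooled` (list `n`, `mean_m`,
#'   `sd_m`), `curve` (data frame `error_m`, `fraction`, nondecreasing and
#'   ending at 1).
#' @export
accuracy_summary <- function(errors) {
  if (is.numeric(errors))
    errors <- data.frame(tag_id = "all", error_m = errors)
  stopifnot(is.data.frame(errors),
            all(c("tag_id", "error_m") %in% names(errors)),
            nrow(errors) >= 1L, all(errors$error_m >= 0))
  per_tag <- do.call(rbind, lapply(split(errors$error_m, errors$tag_id),
    function(e) data.frame(n = length(e), mean_m = mean(e),
                           sd_m = stats::sd(e))))
  per_tag <- data.frame(tag_id = rownames(per_tag), per_tag,
                        stringsAsFactors = FALSE)
  rownames(per_tag) <- NULL
  e <- errors$error_m
  xs <- sort(unique(e))
  curve <- data.frame(error_m = xs,
                      fraction = vapply(xs, function(v) mean(e <= v),
                                        numeric(1)))
  structure(list(per_tag = per_tag,
                 pooled = list(n = length(e), mean_m = mean(e),
                               sd_m = stats::sd(e)),
                 curve = curve),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("<accuracy_summary> %d events, %.2f +/- %.2f m pooled\n",
              x$pooled$n, x$pooled$mean_m,
              if (is.na(x$pooled$sd_m)) 0 else x$pooled$sd_m))
  print(x$per_tag, ...)
  invisible(x)
}

#' Occupancy map of a decoded track
#'
#' Relative frequency of presence at each mapping point: the fraction of
#' track windows decoded to the point.
#'
#' @param track A `cow_track`.
#' @param map The corresponding [barn_map()].
#' @return Numeric vector of length K summing to 1.
#' @export
occupancy_map <- function(track, map) {
  stopifnot(is.data.frame(track), inherits(map, "barn_map"),
            nrow(track) >= 1L)
  tabulate(track$point, nbins = nrow(map$points)) / nrow(track)
}

#' Time distribution over barn zones
#'
#' Aggregates the occupancy map by the zone labels of the mapping points;
#' points carrying no zone fall into `"unassigned"`.
#'
#' @param track A `cow_track`.
#' @param map The corresponding [barn_map()].
#' @return Named numeric vector of time fractions per zone, summing to 1.
#' @export
zone_time_distribution <- function(track, map) {
  occ <- occupancy_map(track, map)
  out <- tapply(occ, map$points$zone, sum)
  structure(as.numeric(out), names = names(out))
}
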