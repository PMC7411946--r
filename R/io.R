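# File formats (RSS logs and map configs as CSV/YAML) and the end-to-end
# pipeline runner.

#' Read a raw RSS log
#'
#' CSV with columns `timestamp` (epoch seconds, or ISO-8601 parsed as UTC),
#' `tag_id`, `station_id`, `rss_db`; a propagation-experiment log may add
#' `distance_m`. Records are returned time-sorted. Rows with unparseable
#' timestamps or non-numeric RSS abort with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `time` (numeric epoch seconds),
#'   `tag_id`, `station_id`, `rss_db` (and `distance_m` when present).
#' @export
read_rss_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "tag_id", "station_id", "rss_db")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("RSS log %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  ts <- df$timestamp
  if (is.numeric(ts)) {
    time <- as.numeric(ts)
  } else {
    suppressWarnings(num <- as.numeric(ts))
    time <- num
    todo <- is.na(num) & !is.na(ts)
    if (any(todo)) {
      parsed <- tryCatch(
        as.POSIXct(ts[todo], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M:%OS")),
        error = function(e) {
          # per-row salvage so the error can name the offending lines
          as.POSIXct(vapply(ts[todo], function(v) {
            tryCatch(as.numeric(as.POSIXct(v, tz = "UTC",
                                           tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                          "%Y-%m-%d %H:%M:%OS"))),
                     error = function(e2) NA_real_)
          }, numeric(1), USE.NAMES = FALSE), tz = "UTC",
          origin = "1970-01-01")
        })
      time[todo] <- as.numeric(parsed)
    }
  }
  bad <- which(!is.finite(time) | !is.finite(suppressWarnings(
    as.numeric(df$rss_db))))
  if (length(bad))
    stop(sprintf("malformed row(s) in %s at line(s): %s", path,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  out <- data.frame(time = time, tag_id = as.character(df$tag_id),
                    station_id = as.character(df$station_id),
                    rss_db = as.numeric(df$rss_db),
                    stringsAsFactors = FALSE)
  if ("distance_m" %in% names(df)) out$distance_m <- as.numeric(df$distance_m)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a raw RSS log
#'
#' Inverse of [read_rss_log()]; timestamps are written as epoch seconds at
#' 0.1 ms precision.
#'
#' @param records RSS log data frame (`time`, `tag_id`, `station_id`,
#'   `rss_db`, optional `distance_m`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rss_log <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("time", "tag_id", "station_id", "rss_db") %in%
                  names(records)))
  out <- data.frame(timestamp = round(records$time, 4),
                    tag_id = records$tag_id,
                    station_id = records$station_id,
                    rss_db = records$rss_db, stringsAsFactors = FALSE)
  if ("distance_m" %in% names(records)) out$distance_m <- records$distance_m
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a barn map configuration
#'
#' YAML with keys `extents` (xmin/xmax/ymin/ymax), `resolution`,
#' `tag_height`, `stations` (list of id/x/y/z), `obstacles` (list of
#' polylines, each a list of (x, y) pairs) and `zones` (mapping of label to
#' closed polygon). Validation (stations inside extents, positive
#' resolution, well-formed polylines) happens in [barn_map()].
#'
#' @param path Path to the YAML file.
#' @return A [barn_map()] without the RSS lookup table
#'   (see [prepare_barn_map()]).
#' @export
read_map_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("extents", "resolution", "stations")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(sprintf("map config %s is missing key(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  stations <- do.call(rbind, lapply(cfg$stations, function(s) {
    # YAML 1.1 parses a bare `y` key as boolean; map it back
    names(s)[names(s) == "TRUE"] <- "y"
    data.frame(id = as.character(s$id), x = as.numeric(s$x),
               y = as.numeric(s$y), z = as.numeric(s$z),
               stringsAsFactors = FALSE)
  }))
  barn_map(extents = cfg$extents,
           stations = stations,
           obstacles = if (is.null(cfg$obstacles)) list() else cfg$obstacles,
           zones = if (is.null(cfg$zones)) list() else cfg$zones,
           resolution = cfg$resolution,
           tag_height = if (is.null(cfg$tag_height)) 1.5 else cfg$tag_height,
           name = if (is.null(cfg$name)) "barn" else cfg$name)
}

#' Write a barn map configuration
#'
#' @param map A [barn_map()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_map_config <- function(map, path) {
  stopifnot(inherits(map, "barn_map"))
  poly_list <- function(m) lapply(seq_len(nrow(m)),
                                  function(i) as.numeric(m[i, ]))
  cfg <- list(
    name = map$name,
    extents = map$extents,
    resolution = map$resolution,
    tag_height = map$tag_height,
    stations = lapply(seq_len(nrow(map$stations)), function(i)
      list(id = map$stations$id[i], x = map$stations$x[i],
           y = map$stations$y[i], z = map$stations$z[i])),
    obstacles = lapply(map$obstacles, poly_list),
    zones = lapply(map$zones, poly_list))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write / read a decoded track
#'
#' Track CSV with columns `t_start`, `tag_id`, `point_index`, `x`, `y`.
#'
#' @param track A `cow_track` from [localize()].
#' @param path CSV path.
#' @return `write_track()` returns `path` invisibly; `read_track()` the
#'   track data frame.
#' @export
write_track <- function(track, path) {
  stopifnot(is.data.frame(track),
            all(c("tag_id", "t_start", "point", "x", "y") %in% names(track)))
  utils::write.csv(
    data.frame(t_start = track$t_start, tag_id = track$tag_id,
               point_index = track$point, x = track$x, y = track$y),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(tag_id = as.character(df$tag_id),
                    t_start = as.numeric(df$t_start),
                    point = as.integer(df$point_index),
                    x = as.numeric(df$x), y = as.numeric(df$y),
                    stringsAsFactors = FALSE)
  class(out) <- c("cow_track", "data.frame")
  out
}

#' Run the full localization pipeline
#'
#' Filter, fold, localize and (optionally) evaluate in one call, writing
#' the decoded track, a JSON accuracy report and a JSON run log.
#'
#' @param config Either a path to a YAML run configuration or a list with
#'   elements: `rss` (RSS log CSV), `map` (map config YAML), optional
#'   `ref` (reference events CSV with `tag_id`, `t_start`, `t_end`,
#'   `point`), `out_dir` (default `"."`), `filter`, `window`, `q`, `fold`,
#'   `shifted`, `min_stations`, `model` (list with `n`, `a0`).
#' @param quiet Suppress stage messages (default `FALSE`).
#' @return Invisibly, a list with the decoded `track`, the
#'   `accuracy_summary` (or `NULL`) and the written `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$rss), !is.null(config$map))
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", label,
                   conditionMessage(e)), call. = FALSE))
  }
  cfg <- utils::modifyList(
    list(filter = "mean", window = 10, q = 1e-5, fold = 5, shifted = TRUE,
         min_stations = 3, out_dir = "."), config)
  if (!is.null(cfg$ref) && !file.exists(cfg$ref))
    stop(sprintf("pipeline stage 'evaluate' failed: no such reference file: %s",
                 cfg$ref), call. = FALSE)
  model <- if (is.null(cfg$model)) default_propagation_model() else
    propagation_model(cfg$model$n, cfg$model$a0)

  records <- stage("read", read_rss_log(cfg$rss))
  say("read", "%d records, %d tag(s)", nrow(records),
      length(unique(records$tag_id)))
  map <- stage("map", prepare_barn_map(read_map_config(cfg$map), model))
  say("map", "%d mapping points, %d stations", nrow(map$points),
      nrow(map$stations))
  track <- stage("localize", localize(
    records, map, filter = cfg$filter, window = cfg$window, q = cfg$q,
    fold = cfg$fold, shifted = cfg$shifted, min_stations = cfg$min_stations))
  say("localize", "%d windows decoded", nrow(track))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(track = file.path(cfg$out_dir, "track.csv"),
                log = file.path(cfg$out_dir, "run_log.json"))
  write_track(track, paths$track)

  summary <- NULL
  if (!is.null(cfg$ref)) {
    refs <- stage("evaluate", utils::read.csv(cfg$ref,
                                              stringsAsFactors = FALSE))
    errs <- stage("evaluate", localization_errors(track, refs, map))
    summary <- stage("evaluate", accuracy_summary(errs))
    paths$report <- file.path(cfg$out_dir, "report.json")
    jsonlite::write_json(list(
      per_tag = summary$per_tag, pooled = summary$pooled,
      curve = summary$curve), paths$report, auto_unbox = TRUE, digits = NA)
    say("evaluate", "%d events, pooled %.2f +/- %.2f m", summary$pooled$n,
        summary$pooled$mean_m, summary$pooled$sd_m)
  }
  jsonlite::write_json(list(
    package = "barnloc",
    version = as.character(utils::packageVersion("barnloc")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    model = list(n = model$n, a0 = model$a0)),
    paths$log, auto_unbox = TRUE, digits = NA)
  invisible(list(track = track, summary = summary, paths = paths))
}
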