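#' @name rss-filters
#' @title RSS stream smoothing
#'
#' @description Smoothing of a single raw 5 Hz RSS stream before folding into
#' observation windows. `mean_filter()` and `median_filter()` use a centered
#' time window of the given width, truncated at the series edges; output
#' timestamps equal input timestamps. `kalman_filter()` runs a linear
#' constant-velocity Kalman recursion on the RSS with state (level, slope),
#' transition \eqn{F = [[1, \Delta t], [0, 1]]}, observation \eqn{H = [1, 0]},
#' process noise \eqn{Q = q I_2} and measurement variance \eqn{R = r}. The
#' state is initialized at (first observation, 0) with unit covariance and a
#' predict/update step is applied for every sample, the first included.
#'
#' @param t Timestamps in seconds, strictly increasing.
#' @param x RSS values in dB, same length as `t`.
#' @param window Window width in seconds (> 0); samples within
#'   `window / 2` of the output timestamp (inclusive) are aggregated.
#' @param dt Nominal sampling interval in seconds (default 0.2, the 5 Hz
#'   advertisement period).
#' @param q Process-noise scale (> 0).
#' @param r Measurement-noise variance (> 0, default 1).
#' @return Filtered values, same length and timestamps as the input. An
#'   empty series yields an empty result.
NULL

.check_series <- function(t, x) {
  stopifnot(is.numeric(t), is.numeric(x), length(t) == length(x))
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
}

# inclusive centered window indices [lo, hi] around each sample
.window_bounds <- function(t, window) {
  half <- window / 2 + 1e-9
  list(lo = findInterval(t - half, t) + 1L,
       hi = findInterval(t + half, t))
}

#' @rdname rss-filters
#' @export
mean_filter <- function(t, x, window) {
  .check_series(t, x)
  stopifnot(window > 0)
  if (length(x) == 0L) return(numeric(0))
  b <- .window_bounds(t, window)
  cs <- cumsum(x)
  lo0 <- numeric(length(x))
  inner <- b$lo > 1L
  lo0[inner] <- cs[b$lo[inner] - 1L]
  (cs[b$hi] - lo0) / (b$hi - b$lo + 1L)
}

#' @rdname rss-filters
#' @export
median_filter <- function(t, x, window) {
  .check_series(t, x)
  stopifnot(window > 0)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  b <- .window_bounds(t, window)
  vapply(seq_len(n),
         function(i) stats::median(x[b$lo[i]:b$hi[i]]),
         numeric(1))
}

#' @rdname rss-filters
#' @export
kalman_filter <- function(t, x, q, dt = 0.2, r = 1) {
  .check_series(t, x)
  stopifnot(q > 0, dt > 0, r > 0)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (any(!is.finite(x)))
    stop("non-finite RSS values in input", call. = FALSE)
  # state (level s1, slope s2); covariance entries p11, p12, p22
  s1 <- x[1]; s2 <- 0
  p11 <- 1; p12 <- 0; p22 <- 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    # predict
    s1 <- s1 + dt * s2
    a11 <- p11 + dt * (p12 + p12 + dt * p22) + q
    a12 <- p12 + dt * p22
    a22 <- p22 + q
    # update with scalar observation
    S <- a11 + r
    k1 <- a11 / S
    k2 <- a12 / S
    y <- x[i] - s1
    s1 <- s1 + k1 * y
    s2 <- s2 + k2 * y
    p11 <- (1 - k1) * a11
    p12 <- (1 - k1) * a12
    p22 <- a22 - k2 * a12
    out[i] <- s1
  }
  out
}

#' Filter an RSS log per tag and station
#'
#' Applies one of the smoothing filters independently to each
#' (tag, station) stream of a raw RSS log.
#'
#' @param records RSS log data frame with columns `time`, `tag_id`,
#'   `station_id`, `rss_db` (see [read_rss_log()]).
#' @param method One of `"mean"`, `"median"`, `"kalman"`, `"none"`.
#' @param window Window width in seconds for mean/median (default 10 s, the
#'   pipeline default).
#' @param q,r,dt Kalman parameters, see [kalman_filter()].
#' @return The records with `rss_db` replaced by its filtered value.
#' @export
filter_rss <- function(records, method = c("mean", "median", "kalman", "none"),
                       window = 10, q = 1e-5, r = 1, dt = 0.2) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records),
            all(c("time", "tag_id", "station_id", "rss_db") %in% names(records)))
  if (method == "none" || nrow(records) == 0L) return(records)
  key <- interaction(records$tag_id, records$station_id, drop = TRUE)
  for (g in levels(key)) {
    idx <- which(key == g)
    idx <- idx[order(records$time[idx])]
    tt <- records$time[idx]
    xx <- records$rss_db[idx]
    records$rss_db[idx] <- switch(method,
      mean = mean_filter(tt, xx, window),
      median = median_filter(tt, xx, window),
      kalman = kalman_filter(tt, xx, q = q, dt = dt, r = r))
  }
  records
}

#' Fold an RSS log into observation windows
#'
#' Aggregates the raw stream into non-overlapping windows of `fold` seconds
#' by per-station averaging; the windows are the time step of the
#' hidden-Markov decoder. Windows are aligned to
#' `t0 = floor(min(time) / fold) * fold` over the whole batch, so every input
#' sample belongs to exactly one window. A station with no sample in a
#' window is absent from that window's heard set.
#'
#' @param records RSS log data frame (`time`, `tag_id`, `station_id`,
#'   `rss_db`).
#' @param fold Window length in seconds (default 5).
#' @return Data frame of class `rss_windows` with columns `tag_id`,
#'   `t_start`, `station_id`, `rss_db` (window mean) and `n` (sample count),
#'   sorted by tag and time; the fold length is kept in attribute `"fold"`.
#' @export
fold_windows <- function(records, fold = 5) {
  stopifnot(is.data.frame(records), fold > 0,
            all(c("time", "tag_id", "station_id", "rss_db") %in% names(records)))
  if (nrow(records) == 0L) {
    out <- data.frame(tag_id = character(0), t_start = numeric(0),
                      station_id = character(0), rss_db = numeric(0),
                      n = integer(0))
    attr(out, "fold") <- fold
    class(out) <- c("rss_windows", "data.frame")
    return(out)
  }
  t0 <- floor(min(records$time) / fold) * fold
  t_start <- t0 + floor((records$time - t0) / fold) * fold
  key <- paste(records$tag_id, format(t_start, nsmall = 6), records$station_id,
               sep = "\r")
  m <- tapply(records$rss_db, key, mean)
  n <- tapply(records$rss_db, key, length)
  first <- !duplicated(key)
  kf <- key[first]
  out <- data.frame(tag_id = records$tag_id[first],
                    t_start = t_start[first],
                    station_id = records$station_id[first],
                    rss_db = as.numeric(m[kf]),
                    n = as.integer(n[kf]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag_id, out$t_start, out$station_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fold") <- fold
  class(out) <- c("rss_windows", "data.frame")
  out
}
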