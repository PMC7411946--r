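# Per-window localization error surfaces, emission probabilities and
# Viterbi decoding over the barn transition graph.

#' Localization error surface for one observation window
#'
#' For every mapping point k the squared-error fit between the window's
#' measured RSS and the lookup-table RSS, summed over the stations heard in
#' the window. With `shifted = TRUE` (the system default) both sides are
#' first centered by their means over the heard subset:
#' \deqn{Err_k = \sum_i ((RSS_{mes,i} - N_{mes}) - (RSS_{map,k,i} - N_{pm,k}))^2,}
#' which cancels any common per-tag / per-station level offset. With
#' `shifted = FALSE` the raw squared differences are summed.
#'
#' @param rss_by_station Named numeric vector: mean RSS (dB) per heard
#'   station; names are station ids present in the map.
#' @param map A prepared [barn_map()] (see [prepare_barn_map()]).
#' @param shifted Use the shift-invariant error (default `TRUE`).
#' @param min_stations Minimum heard stations for a locatable window
#'   (default 3); below this the window is flagged unlocatable and `NULL`
#'   is returned with a warning.
#' @return An object of class `rss_error_surface`: list with `err`
#'   (non-negative vector over the K mapping points), `n_stations_used`,
#'   `shifted`; or `NULL` for an unlocatable window.
#' @export
error_surface <- function(rss_by_station, map, shifted = TRUE,
                          min_stations = 3) {
  stopifnot(inherits(map, "barn_map"), is.numeric(rss_by_station))
  if (is.null(map$rss_map))
    stop("map has no RSS lookup table; call prepare_barn_map() first",
         call. = FALSE)
  heard <- names(rss_by_station)
  if (is.null(heard) || any(!nzchar(heard)))
    stop("`rss_by_station` must be named by station id", call. = FALSE)
  cols <- match(heard, colnames(map$rss_map))
  if (anyNA(cols))
    stop(sprintf("unknown station id(s): %s",
                 paste(heard[is.na(cols)], collapse = ", ")), call. = FALSE)
  if (length(heard) < min_stations) {
    warning(sprintf("window heard by %d station(s) < %d: unlocatable",
                    length(heard), min_stations), call. = FALSE)
    return(NULL)
  }
  R <- map$rss_map[, cols, drop = FALSE]
  m <- as.numeric(rss_by_station)
  if (shifted) {
    m <- m - mean(m)
    R <- R - rowMeans(R)
  }
  err <- colSums((t(R) - m)^2)
  structure(list(err = pmax(err, 0), n_stations_used = length(heard),
                 shifted = shifted),
            class = "rss_error_surface")
}

#' Best-fitting mapping point of an error surface
#'
#' @param surface An `rss_error_surface` (or bare numeric error vector).
#' @return Index of the minimum error; ties broken by the lowest index.
#' @export
best_point <- function(surface) {
  err <- if (inherits(surface, "rss_error_surface")) surface$err else surface
  stopifnot(is.numeric(err), length(err) >= 1L)
  which.min(err)
}

#' Emission probabilities from an error surface
#'
#' The hidden-Markov emission weight of each mapping point is the
#' reciprocal localization error, floored at `eps` and normalized to sum
#' to one.
#'
#' @param surface An `rss_error_surface` (or bare numeric error vector).
#' @param eps Floor applied to the error before inversion (default 1e-9).
#' @return Probability vector over the mapping points (sums to 1).
#' @export
emission_probabilities <- function(surface, eps = 1e-9) {
  err <- if (inherits(surface, "rss_error_surface")) surface$err else surface
  stopifnot(is.numeric(err), length(err) >= 1L, eps > 0)
  w <- 1 / pmax(err, eps)
  w / sum(w)
}

#' Most probable mapping-point path (Viterbi)
#'
#' Maximum-a-posteriori hidden-state path of the localization HMM, computed
#' in the log domain. Emission rows that are all zero (or `NA`) are treated
#' as uninformative (uniform), so such windows are bridged by the
#' transition prior alone. Ties are broken by the lowest point index.
#'
#' @param emissions T x K matrix: one row of emission probabilities per
#'   observation window.
#' @param tm K x K row-stochastic transition matrix
#'   (see [build_transition_matrix()]).
#' @param prior Initial state distribution (default uniform).
#' @return Integer vector of length T of mapping-point indices.
#' @export
viterbi_decode <- function(emissions, tm, prior = NULL) {
  emissions <- as.matrix(emissions)
  TT <- nrow(emissions); K <- ncol(emissions)
  stopifnot(TT >= 1L, is.matrix(tm), nrow(tm) == K, ncol(tm) == K)
  if (is.null(prior)) prior <- rep(1 / K, K)
  stopifnot(length(prior) == K)
  bad <- !is.finite(emissions)
  if (any(bad)) emissions[bad] <- 0
  dead <- rowSums(emissions) <= 0
  if (any(dead)) emissions[dead, ] <- 1 / K
  logE <- log(pmax(emissions, 1e-300))
  logT <- log(tm)                      # -Inf marks forbidden passages
  logT[is.nan(logT)] <- -Inf
  delta <- log(pmax(prior, 1e-300)) + logE[1L, ]
  psi <- matrix(1L, TT, K)
  if (TT > 1L) {
    for (t in 2:TT) {
      s <- delta + logT                # s[i, j] = delta[i] + log tm[i, j]
      am <- max.col(t(s), ties.method = "first")
      delta <- s[cbind(am, seq_len(K))] + logE[t, ]
      psi[t, ] <- am
    }
  }
  path <- integer(TT)
  path[TT] <- which.max(delta)
  if (TT > 1L) {
    for (t in (TT - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  }
  path
}

# Emission matrix for one tag's folded windows. Windows are grouped by
# heard-station pattern so the centered squared-error surfaces can be
# computed by dense matrix algebra per group. The window axis is the full
# fold-spaced sequence: intervals with no reception at all become
# uninformative rows so decoder steps always span one fold interval.
.emissions_for_tag <- function(wdf, map, shifted, min_stations, eps,
                               fold = 5) {
  t_starts <- seq(min(wdf$t_start), max(wdf$t_start), by = fold)
  sids <- colnames(map$rss_map)
  W <- length(t_starts); K <- nrow(map$points)
  M <- matrix(NA_real_, W, length(sids), dimnames = list(NULL, sids))
  M[cbind(match(wdf$t_start, t_starts), match(wdf$station_id, sids))] <-
    wdf$rss_db
  em <- matrix(NA_real_, W, K)
  heard_n <- rowSums(!is.na(M))
  pattern <- apply(!is.na(M), 1L, paste, collapse = "")
  for (p in unique(pattern)) {
    rows <- which(pattern == p)
    cols <- which(!is.na(M[rows[1L], ]))
    if (length(cols) < min_stations) next
    A <- M[rows, cols, drop = FALSE]
    B <- map$rss_map[, cols, drop = FALSE]
    if (shifted) {
      A <- A - rowMeans(A)
      B <- B - rowMeans(B)
    }
    # E[w, k] = || A_w - B_k ||^2
    E <- pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0)
    Wt <- 1 / pmax(E, eps)
    em[rows, ] <- Wt / rowSums(Wt)
  }
  locatable <- !is.na(em[, 1L])
  list(t_start = t_starts, emissions = em, locatable = locatable,
       heard_n = heard_n)
}

#' Localize tags from a raw RSS log
#'
#' The full decoding pipeline: per-station smoothing of the 5 Hz stream,
#' folding into 5-s observation windows, shift-invariant error surfaces and
#' emission probabilities over the mapping points, and Viterbi smoothing
#' over the barn-structure transition matrix. Tags are decoded
#' independently. Windows heard by fewer than `min_stations` stations are
#' bridged by the transition prior alone.
#'
#' @param records RSS log data frame (`time`, `tag_id`, `station_id`,
#'   `rss_db`).
#' @param map A [barn_map()]; prepared with the default propagation model
#'   if the lookup table is missing.
#' @param filter Smoothing method applied before folding: `"mean"`
#'   (default), `"median"`, `"kalman"` or `"none"`.
#' @param window Mean/median filter window in seconds (default 10).
#' @param q,r Kalman parameters (see [kalman_filter()]).
#' @param fold Observation-window length in seconds (default 5).
#' @param shifted Use the shift-invariant error surface (default `TRUE`).
#' @param min_stations Minimum heard stations per locatable window
#'   (default 3).
#' @param eps Emission error floor (default 1e-9).
#' @param smooth Apply Viterbi trajectory smoothing (default `TRUE`).
#'   `FALSE` returns the per-window best-fitting point instead (unlocatable
#'   windows carry the previous locatable point), a useful diagnostic
#'   baseline when emissions are nearly flat.
#' @return Data frame of class `cow_track`: `tag_id`, `t_start`, `point`,
#'   `x`, `y`, `locatable`, sorted by tag and time.
#' @export
localize <- function(records, map, filter = c("mean", "median", "kalman",
                                              "none"),
                     window = 10, q = 1e-5, r = 1, fold = 5, shifted = TRUE,
                     min_stations = 3, eps = 1e-9, smooth = TRUE) {
  filter <- match.arg(filter)
  stopifnot(inherits(map, "barn_map"))
  if (is.null(map$rss_map)) map <- prepare_barn_map(map)
  recs <- filter_rss(records, method = filter, window = window, q = q, r = r)
  wins <- fold_windows(recs, fold = fold)
  out <- list()
  for (tg in unique(wins$tag_id)) {
    wdf <- wins[wins$tag_id == tg, , drop = FALSE]
    e <- .emissions_for_tag(wdf, map, shifted, min_stations, eps,
                            fold = fold)
    if (!any(e$locatable)) {
      warning(sprintf("tag %s has no locatable windows: empty track", tg),
              call. = FALSE)
      next
    }
    if (smooth) {
      path <- viterbi_decode(e$emissions, map$tm)
    } else {
      path <- apply(e$emissions, 1L, which.max)
      path[!e$locatable] <- NA_integer_
      # hold the last locatable fix through unlocatable windows
      for (i in seq_along(path)) {
        if (is.na(path[i])) path[i] <- if (i > 1L) path[i - 1L] else 1L
      }
    }
    out[[tg]] <- data.frame(tag_id = tg, t_start = e$t_start, point = path,
                            x = map$points$x[path], y = map$points$y[path],
                            locatable = e$locatable,
                            stringsAsFactors = FALSE)
  }
  track <- if (length(out)) do.call(rbind, out) else
    data.frame(tag_id = character(0), t_start = numeric(0),
               point = integer(0), x = numeric(0), y = numeric(0),
               locatable = logical(0))
  rownames(track) <- NULL
  class(track) <- c("cow_track", "data.frame")
  track
}
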