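#' Log-distance path-loss model
#'
#' Construct the RSS propagation model \eqn{RSS = -10 n \log_{10}(D) + A_0},
#' where \eqn{D} is the tag--station distance in metres, \eqn{n} the path-loss
#' exponent and \eqn{A_0} the path-loss constant, i.e. the predicted RSS (dB)
#' at the 1 m reference distance.
#'
#' @param n Path-loss exponent (dimensionless, finite).
#' @param a0 Path-loss constant in dB (finite).
#' @return An object of class `propagation_model`.
#' @seealso [predict_rss()], [fit_propagation_model()],
#'   [default_propagation_model()]
#' @export
#' @examples
#' m <- propagation_model(n = 2, a0 = -40)
#' predict_rss(m, c(1, 10))
propagation_model <- function(n, a0) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(a0), length(a0) == 1L, is.finite(a0))
  structure(list(n = as.numeric(n), a0 = as.numeric(a0)),
            class = "propagation_model")
}

#' Default barn propagation model
#'
#' The pooled open-space model used by the localization system:
#' n = 0.84, A0 = -48.77 dB.
#'
#' @return A `propagation_model`.
#' @export
default_propagation_model <- function() {
  propagation_model(n = 0.84, a0 = -48.77)
}

#' @export
print.propagation_model <- function(x, ...) {
  cat(sprintf("<propagation_model> RSS = -10 * %.4g * log10(D) %+.4g dB\n",
              x$n, x$a0))
  invisible(x)
}

#' Predict RSS at a distance
#'
#' @param model A [propagation_model()].
#' @param distance Distance(s) in metres; must be positive and finite.
#' @return Predicted RSS in dB, same length as `distance`.
#' @export
predict_rss <- function(model, distance) {
  stopifnot(inherits(model, "propagation_model"), is.numeric(distance))
  if (length(distance) == 0L) return(numeric(0))
  if (any(!is.finite(distance) | distance <= 0))
    stop("`distance` must be positive and finite", call. = FALSE)
  -10 * model$n * log10(distance) + model$a0
}

#' Fit the path-loss model by least squares
#'
#' Ordinary least-squares regression of measured RSS on
#' \eqn{-10\log_{10}(D)} with intercept: the slope estimates the path-loss
#' exponent n and the intercept the constant A0. Coefficient standard errors
#' are the usual OLS standard errors.
#'
#' @param distance Distances in metres (positive); at least two distinct
#'   values are required.
#' @param rss Measured RSS in dB, same length as `distance`.
#' @return An object of class `propagation_fit`: a list with elements
#'   `model` (the fitted [propagation_model()]), `r_squared`, `n_std`,
#'   `a0_std`, and `fit` (the underlying `lm` object).
#' @export
fit_propagation_model <- function(distance, rss) {
  stopifnot(is.numeric(distance), is.numeric(rss),
            length(distance) == length(rss))
  if (length(distance) < 2L)
    stop("need at least two samples to fit the path-loss model", call. = FALSE)
  if (any(!is.finite(distance) | distance <= 0))
    stop("`distance` must be positive and finite", call. = FALSE)
  if (length(unique(distance)) < 2L)
    stop("degenerate design: all samples at a single distance", call. = FALSE)
  x <- -10 * log10(distance)
  fit <- stats::lm(rss ~ x)
  # noiseless calibration data fits perfectly; that is fine here
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  structure(list(
    model = propagation_model(n = unname(stats::coef(fit)[["x"]]),
                              a0 = unname(stats::coef(fit)[["(Intercept)"]])),
    r_squared = sm$r.squared,
    n_std = unname(co["x", "Std. Error"]),
    a0_std = unname(co["(Intercept)", "Std. Error"]),
    fit = fit
  ), class = "propagation_fit")
}

#' @export
print.propagation_fit <- function(x, ...) {
  cat(sprintf(
    "<propagation_fit> n = %.3f +/- %.3f, A0 = %.2f +/- %.2f dB, R^2 = %.3f\n",
    x$model$n, x$n_std, x$model$a0, x$a0_std, x$r_squared))
  invisible(x)
}

#' Mean RSS per distance
#'
#' Averages the raw RSS samplings of a propagation experiment per distance
#' bin, the reduction used before curve inspection and model fitting.
#'
#' @param records Data frame with columns `distance_m` and `rss_db`.
#' @return Data frame with columns `distance_m`, `rss_db` (the mean) and `n`
#'   (samples per bin), sorted by distance. Empty groups cannot arise and so
#'   never appear.
#' @export
aggregate_distance_rss <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("distance_m", "rss_db") %in% names(records)))
  if (nrow(records) == 0L)
    stop("`records` must be non-empty", call. = FALSE)
  m <- tapply(records$rss_db, records$distance_m, mean)
  n <- tapply(records$rss_db, records$distance_m, length)
  out <- data.frame(distance_m = as.numeric(names(m)),
                    rss_db = as.numeric(m),
                    n = as.integer(n))
  out[order(out$distance_m), , drop = FALSE]
}

#' Between-tag and between-station RSS variability
#'
#' Quantifies the spread of the per-tag and per-station average propagation
#' curves. For every (tag, distance) the RSS is averaged over stations and
#' samples; the SD across tags is taken per distance bin and averaged over
#' bins, yielding `per_tag_std`. `per_station_std` is computed analogously
#' with the roles of tags and stations exchanged. Sample SD (n - 1) is used.
#'
#' @param records Data frame with columns `tag_id`, `station_id`,
#'   `distance_m`, `rss_db`.
#' @return A list of class `variability_stats` with numeric elements
#'   `per_tag_std` and `per_station_std` (dB). A component is `NA` (with a
#'   warning) when fewer than two tags or stations are present.
#' @export
variability_stats <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("tag_id", "station_id", "distance_m", "rss_db") %in%
                  names(records)))
  if (nrow(records) == 0L)
    stop("`records` must be non-empty", call. = FALSE)
  spread <- function(group) {
    ids <- unique(records[[group]])
    if (length(ids) < 2L) {
      warning(sprintf("fewer than two distinct %s values: STD undefined",
                      group), call. = FALSE)
      return(NA_real_)
    }
    # per-(group, distance) mean curve, then SD across curves per distance
    mu <- tapply(records$rss_db,
                 list(records[[group]], records$distance_m),
                 mean)
    sds <- apply(mu, 2L, stats::sd, na.rm = TRUE)
    mean(sds, na.rm = TRUE)
  }
  structure(list(per_tag_std = spread("tag_id"),
                 per_station_std = spread("station_id")),
            class = "variability_stats")
}

#' @export
print.variability_stats <- function(x, ...) {
  cat(sprintf("<variability_stats> per-tag STD %.2f dB, per-station STD %.2f dB\n",
              x$per_tag_std, x$per_station_std))
  invisible(x)
}
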