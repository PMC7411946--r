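# Base-graphics views of the evaluation outputs.

#' Plot the cumulative error curve
#'
#' Empirical cumulative percentage of reference events with localization
#' error at or below each value, the standard accuracy display for indoor
#' positioning systems.
#'
#' @param summary An [accuracy_summary()].
#' @param ... Passed to [graphics::plot()].
#' @return The summary, invisibly.
#' @export
plot_cumulative_error <- function(summary, ...) {
  stopifnot(inherits(summary, "accuracy_summary"))
  cv <- summary$curve
  graphics::plot(c(0, cv$error_m), c(0, cv$fraction * 100), type = "s",
                 xlab = "Localization error [m]",
                 ylab = "Cumulative percentage [%]",
                 ylim = c(0, 100), ...)
  graphics::abline(h = c(50, 90), lty = 3, col = "grey60")
  invisible(summary)
}

#' Plot an occupancy heat map
#'
#' Relative presence frequency at each mapping point on the barn floor
#' plan, with stations overlaid.
#'
#' @param occupancy Vector from [occupancy_map()].
#' @param map The corresponding [barn_map()].
#' @param ... Passed to [graphics::plot()].
#' @return `occupancy`, invisibly.
#' @export
plot_occupancy <- function(occupancy, map, ...) {
  stopifnot(inherits(map, "barn_map"),
            length(occupancy) == nrow(map$points))
  pal <- grDevices::hcl.colors(32, "YlOrRd", rev = TRUE)
  idx <- pmin(pmax(ceiling(occupancy / max(occupancy, 1e-12) * 32), 1L), 32L)
  graphics::plot(map$points$x, map$points$y, pch = 15, col = pal[idx],
                 cex = 1.2, asp = 1, xlab = "x [m]", ylab = "y [m]", ...)
  for (o in map$obstacles)
    graphics::lines(o[, 1], o[, 2], lwd = 2, col = "grey30")
  graphics::points(map$stations$x, map$stations$y, pch = 17, col = "blue")
  invisible(occupancy)
}
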