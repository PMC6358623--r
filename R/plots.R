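#' Plot per-ring density differences against distance from roads
#'
#' Draws the mean actual-minus-copy sign-density difference per ring,
#' marking significant rings with filled points and the estimated effect
#' zone with a vertical line.
#'
#' @param results data.frame from [ring_test_table()].
#' @param zone optional result of [effect_zone()] (draws the zone edge).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `results`.
#' @export
plot_ring_differences <- function(results, zone = NULL, ...) {
  graphics::plot(results$distance_m, results$diff, type = "b",
                 pch = ifelse(results$significant, 19, 1),
                 xlab = "Distance from road (m)",
                 ylab = expression(paste("Density difference (signs/",
                                         km^2, ")")), ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(zone) && zone$zone_m > 0)
    graphics::abline(v = zone$zone_m, lty = 2, col = "red")
  invisible(results)
}
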