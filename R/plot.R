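#' Plot population curves of area and aspect ratio
#'
#' Mean area and AR over scored spores against time, with a shaded standard
#' error band, mirroring the standard presentation of germination time
#' courses.
#'
#' @param curves data frame from [population_curves()].
#' @param which `"area"` or `"ar"`.
#' @param col line color.
#' @param add add to an existing plot.
#' @param ... passed to [plot()].
#' @return Invisibly, `curves`.
#' @export
plot_population_curves <- function(curves, which = c("area", "ar"),
                                   col = "#2166ac", add = FALSE, ...) {
  which <- match.arg(which)
  y <- if (which == "area") curves$area_mean else curves$ar_mean
  se <- if (which == "area") curves$area_se else curves$ar_se
  ylab <- if (which == "area") "cell area (µm²)" else "aspect ratio"
  if (!add)
    plot(curves$time_min, y, type = "n", xlab = "time (min)", ylab = ylab, ...)
  ok <- !is.na(se)
  polygon(c(curves$time_min[ok], rev(curves$time_min[ok])),
          c(y[ok] - se[ok], rev(y[ok] + se[ok])),
          col = adjustcolor(col, 0.25), border = NA)
  lines(curves$time_min, y, col = col, lwd = 2)
  invisible(curves)
}
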