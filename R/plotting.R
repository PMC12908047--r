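#' @include AllClasses.R
NULL

#' Plot an activity map
#'
#' Displays the sigma heatmap with image-style orientation (row 0 at the
#' top) and optionally overlays detected hotspot ROIs.
#'
#' @param x an \linkS4class{ActivityMap}
#' @param y unused
#' @param hotspots optional list of \linkS4class{Hotspot} to overlay
#' @param ... passed to \code{\link[graphics]{image}}
#' @return invisibly, \code{x}
#' @export
setMethod("plot", signature(x = "ActivityMap", y = "missing"),
  function(x, y, hotspots = list(), ...) {
    s <- x@sigma
    graphics::image(x = 0:(ncol(s) - 1), y = 0:(nrow(s) - 1),
                    z = t(s)[, rev(seq_len(nrow(s))), drop = FALSE],
                    col = grDevices::hcl.colors(64, "inferno"),
                    xlab = "col (px)", ylab = "row (px, flipped)",
                    useRaster = TRUE, ...)
    for (h in hotspots) {
      th <- seq(0, 2 * pi, length.out = 64)
      graphics::lines(h@roi@center[2L] + h@roi@radius * cos(th),
                      nrow(s) - 1 - h@roi@center[1L] +
                        h@roi@radius * sin(th),
                      col = "white", lwd = 1.5)
    }
    invisible(x)
  })

#' Plot a phase-lock curve
#'
#' @param x a \linkS4class{PhaseLockCurve}
#' @param y unused
#' @param add add to an existing plot
#' @param col line color
#' @param ... passed to \code{\link[graphics]{lines}} /
#'   \code{\link[graphics]{plot}}
#' @return invisibly, \code{x}
#' @export
setMethod("plot", signature(x = "PhaseLockCurve", y = "missing"),
  function(x, y, add = FALSE, col = "firebrick", ...) {
    if (!add) {
      graphics::plot(x@frequencies, x@response, log = "x", type = "n",
                     xlab = "stimulus frequency (Hz)",
                     ylab = "phase-locked response", ...)
    }
    if (length(x@dispersionLow)) {
      graphics::polygon(c(x@frequencies, rev(x@frequencies)),
                        c(x@dispersionLow, rev(x@dispersionHigh)),
                        border = NA,
                        col = grDevices::adjustcolor(col, 0.25))
    }
    graphics::lines(x@frequencies, x@response, col = col, lwd = 2, ...)
    invisible(x)
  })
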