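#' @include AllClasses.R
NULL

#' @rdname accessor-generics
#' @export
setMethod("frames", "ImageStack", function(x) x@frames)

#' @rdname accessor-generics
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3L])

#' @rdname accessor-generics
#' @export
setMethod("frameRate", "ImageStack", function(x) x@frameRate)

#' @rdname accessor-generics
#' @export
setMethod("pixelPitch", "ImageStack", function(x) x@pixelPitch)

#' @rdname accessor-generics
#' @export
setMethod("zIndex", "ImageStack", function(x) x@zIndex)

#' @rdname accessor-generics
#' @export
setMethod("bitDepth", "ImageStack", function(x) x@bitDepth)

#' @rdname accessor-generics
#' @export
setMethod("frameRate", "CameraModel", function(x) x@frameRate)

#' @rdname accessor-generics
#' @export
setMethod("pixelPitch", "CameraModel", function(x) x@pixelPitch)

#' @rdname accessor-generics
#' @export
setMethod("bitDepth", "CameraModel", function(x) x@bitDepth)

#' @rdname accessor-generics
#' @export
setMethod("traceValues", "Trace", function(x) x@values)

#' @rdname accessor-generics
#' @export
setMethod("sampleRate", "Trace", function(x) x@sampleRate)

#' @rdname accessor-generics
#' @export
setMethod("traceKind", "Trace", function(x) x@kind)

#' @rdname accessor-generics
#' @export
setMethod("traceTimes", "Trace", function(x)
  x@t0 + (seq_along(x@values) - 1) / x@sampleRate)

#' @rdname accessor-generics
#' @export
setMethod("muMap", "ActivityMap", function(x) x@mu)

#' @rdname accessor-generics
#' @export
setMethod("sigmaMap", "ActivityMap", function(x) x@sigma)

#' @rdname accessor-generics
#' @export
setMethod("mapMask", "ActivityMap", function(x) x@mask)

#' @rdname accessor-generics
#' @export
setMethod("roiCenter", "Roi", function(x) x@center)

#' @rdname accessor-generics
#' @export
setMethod("roiRadius", "Roi", function(x) x@radius)

#' @rdname accessor-generics
#' @export
setMethod("roiLabel", "Roi", function(x) x@label)

#' @rdname accessor-generics
#' @export
setMethod("roiCenter", "Hotspot", function(x) x@roi@center)

#' @rdname accessor-generics
#' @export
setMethod("maxCorr", "CorrelationResult", function(x) x@maxCorr)

#' @rdname accessor-generics
#' @export
setMethod("corrLag", "CorrelationResult", function(x) x@lag)

#' @rdname accessor-generics
#' @export
setMethod("isCorrelated", "CorrelationResult", function(x) x@correlated)

#' @rdname accessor-generics
#' @export
setMethod("frequencies", "Spectrum", function(x) x@frequencies)

#' @rdname accessor-generics
#' @export
setMethod("amplitudes", "Spectrum", function(x) x@amplitudes)

#' @rdname accessor-generics
#' @export
setMethod("frequencies", "SweepSegmentation", function(x) x@frequencies)

#' @rdname accessor-generics
#' @export
setMethod("segmentStarts", "SweepSegmentation", function(x) x@starts)

#' @rdname accessor-generics
#' @export
setMethod("segmentLengths", "SweepSegmentation", function(x) x@lengths)

#' @rdname accessor-generics
#' @export
setMethod("frequencies", "PhaseLockCurve", function(x) x@frequencies)

#' @rdname accessor-generics
#' @export
setMethod("response", "PhaseLockCurve", function(x) x@response)

#' Summarize detected hotspots as a data.frame
#'
#' @param hotspots a list of \linkS4class{Hotspot} objects as returned by
#'   \code{\link{detectHotspots}}
#' @return a data.frame with one row per hotspot: centroid (row, col),
#'   ROI center and radius, z index, peak sigma and component area
#' @examples
#' amap <- ActivityMap(mu = matrix(1, 8, 8), sigma = matrix(0, 8, 8),
#'                     mask = matrix(TRUE, 8, 8), normalized = FALSE)
#' hotspotTable(detectHotspots(amap))
#' @export
hotspotTable <- function(hotspots) {
  if (!length(hotspots)) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), zIndex = integer(0),
                      peakSigma = numeric(0), areaPx = integer(0)))
  }
  do.call(rbind, lapply(hotspots, function(h) {
    data.frame(row = h@centroid[1L], col = h@centroid[2L],
               radius = h@roi@radius, zIndex = h@roi@zIndex,
               peakSigma = h@peakSigma, areaPx = h@areaPx)
  }))
}

#' Convert a PhaseLockCurve to a data.frame
#'
#' @param x a \linkS4class{PhaseLockCurve}
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return data.frame with columns \code{frequency_hz}, \code{response},
#'   \code{amplitude_nm_label} and, when repeats were analyzed,
#'   \code{dispersion_low}/\code{dispersion_high}
#' @export
as.data.frame.PhaseLockCurve <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  df <- data.frame(frequency_hz = x@frequencies, response = x@response,
                   amplitude_nm_label = x@amplitudeLabel)
  if (length(x@dispersionLow)) {
    df$dispersion_low <- x@dispersionLow
    df$dispersion_high <- x@dispersionHigh
  }
  df
}
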