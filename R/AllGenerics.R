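#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the core S4 containers. Slot access via
#' \code{@} is considered internal; these are the supported interface.
#'
#' @param x an object of one of the package classes
#' @return the corresponding slot value
#' @name accessor-generics
#' @keywords internal
NULL

#' @rdname accessor-generics
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessor-generics
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessor-generics
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessor-generics
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname accessor-generics
#' @export
setGeneric("zIndex", function(x) standardGeneric("zIndex"))

#' @rdname accessor-generics
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname accessor-generics
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname accessor-generics
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessor-generics
#' @export
setGeneric("traceKind", function(x) standardGeneric("traceKind"))

#' @rdname accessor-generics
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname accessor-generics
#' @export
setGeneric("muMap", function(x) standardGeneric("muMap"))

#' @rdname accessor-generics
#' @export
setGeneric("sigmaMap", function(x) standardGeneric("sigmaMap"))

#' @rdname accessor-generics
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))

#' @rdname accessor-generics
#' @export
setGeneric("roiCenter", function(x) standardGeneric("roiCenter"))

#' @rdname accessor-generics
#' @export
setGeneric("roiRadius", function(x) standardGeneric("roiRadius"))

#' @rdname accessor-generics
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' @rdname accessor-generics
#' @export
setGeneric("maxCorr", function(x) standardGeneric("maxCorr"))

#' @rdname accessor-generics
#' @export
setGeneric("corrLag", function(x) standardGeneric("corrLag"))

#' @rdname accessor-generics
#' @export
setGeneric("isCorrelated", function(x) standardGeneric("isCorrelated"))

#' @rdname accessor-generics
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessor-generics
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname accessor-generics
#' @export
setGeneric("response", function(x) standardGeneric("response"))

#' @rdname accessor-generics
#' @export
setGeneric("segmentStarts", function(x) standardGeneric("segmentStarts"))

#' @rdname accessor-generics
#' @export
setGeneric("segmentLengths", function(x) standardGeneric("segmentLengths"))
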