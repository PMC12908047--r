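#' @include AllClasses.R utils.R synthetic-data.R
NULL

#' Segment a sweep recording into per-frequency steps
#'
#' One segment per frequency step of the stepped sweep; segment i holds
#' \code{round(cyclesPerStep * sampleRate / f_i)} samples, and the segments
#' tile the stimulus duration exactly. Errors if any segment would be
#' shorter than 16 samples (the Fourier projection would be meaningless).
#'
#' @param protocol a \linkS4class{StimulusProtocol} of kind \code{"sweep"}
#' @param sampleRate Hz of the recording to be segmented
#' @return a \linkS4class{SweepSegmentation}
#' @examples
#' p <- StimulusProtocol("sweep", amplitude = 50, sweepStart = 10,
#'                       sweepEnd = 20, nSteps = 2L, stepSpacing = "linear")
#' segmentLengths(segmentSweep(p, 1000))   # 1000, 500
#' @export
segmentSweep <- function(protocol, sampleRate) {
  stopifnot(is(protocol, "StimulusProtocol"))
  if (protocol@kind != "sweep")
    stop("segmentSweep needs a protocol of kind 'sweep'")
  if (sampleRate <= 0) stop("sampleRate must be > 0")
  f <- .sweepFrequencies(protocol)
  len <- as.integer(round(protocol@cyclesPerStep * sampleRate / f))
  if (any(len < 16L))
    stop(sprintf(
      "segment at %.4g Hz would hold only %d samples (minimum 16)",
      f[which.min(len)], min(len)))
  starts <- as.integer(cumsum(c(1L, len[-length(len)])))
  new("SweepSegmentation", starts = starts, lengths = len, frequencies = f,
      sampleRate = as.numeric(sampleRate))
}

## Single-frequency discrete Fourier projection of a mean-subtracted
## segment: 2 |sum_t x_t exp(-i 2 pi f t / fs)| / M. On a segment holding
## an integer number of cycles this equals the FFT bin amplitude; unlike a
## bin lookup it stays exact when rounding makes the cycle count slightly
## non-integer.
.fourierProjection <- function(x, f, fs) {
  m <- length(x)
  x <- x - mean(x)
  t <- 0:(m - 1)
  2 * Mod(sum(x * exp(-2i * pi * f * t / fs))) / m
}

#' Phase-locked response of a trace across a sweep
#'
#' Per sweep step, the amplitude of the trace's frequency component at the
#' stimulus frequency: the mean-subtracted segment is projected onto the
#' exact step frequency (single-frequency discrete Fourier projection).
#'
#' @param trace the recorded \linkS4class{Trace} (bundle displacement or
#'   hotspot delta-I over I), sampled at the segmentation's rate
#' @param seg a \linkS4class{SweepSegmentation}
#' @param amplitudeLabel stimulus amplitude the curve is labeled with (nm)
#' @return a \linkS4class{PhaseLockCurve}
#' @examples
#' p <- StimulusProtocol("sweep", amplitude = 50, sweepStart = 5,
#'                       sweepEnd = 20, nSteps = 3L, cyclesPerStep = 10L)
#' seg <- segmentSweep(p, 1000)
#' stim <- unlist(lapply(seq_along(frequencies(seg)), function(i)
#'   50 * sin(2 * pi * frequencies(seg)[i] *
#'              (0:(segmentLengths(seg)[i] - 1)) / 1000)))
#' pl <- phaseLockedResponse(Trace(stim, 1000, "stimulus_nm"), seg)
#' round(response(pl), 6)   # 50 at every step
#' @export
phaseLockedResponse <- function(trace, seg, amplitudeLabel = NA_real_) {
  stopifnot(is(trace, "Trace"), is(seg, "SweepSegmentation"))
  if (abs(trace@sampleRate - seg@sampleRate) >
      1e-9 * max(trace@sampleRate, seg@sampleRate))
    stop("trace and segmentation sample rates differ")
  total <- seg@starts[length(seg@starts)] + seg@lengths[length(seg@lengths)] - 1L
  if (length(trace@values) < total)
    stop("trace is shorter than the sweep segmentation")
  resp <- vapply(seq_along(seg@starts), function(i) {
    x <- trace@values[seg@starts[i]:(seg@starts[i] + seg@lengths[i] - 1L)]
    .fourierProjection(x, seg@frequencies[i], seg@sampleRate)
  }, numeric(1L))
  new("PhaseLockCurve", frequencies = seg@frequencies, response = resp,
      amplitudeLabel = as.numeric(amplitudeLabel),
      dispersionLow = numeric(0), dispersionHigh = numeric(0))
}

#' Aggregate phase-lock curves across repeat sweeps
#'
#' Averages repeat curves on a shared frequency grid and records the
#' min-max dispersion envelope.
#'
#' @param curves list of \linkS4class{PhaseLockCurve} on identical grids
#' @return a \linkS4class{PhaseLockCurve} with dispersion envelopes
#' @export
aggregateCurves <- function(curves) {
  stopifnot(length(curves) >= 1L)
  f <- curves[[1L]]@frequencies
  for (cv in curves)
    if (!isTRUE(all.equal(cv@frequencies, f)))
      stop("curves must share the same frequency grid")
  if (length(curves) == 1L) return(curves[[1L]])
  m <- do.call(rbind, lapply(curves, function(cv) cv@response))
  new("PhaseLockCurve", frequencies = f, response = colMeans(m),
      amplitudeLabel = curves[[1L]]@amplitudeLabel,
      dispersionLow = apply(m, 2L, min), dispersionHigh = apply(m, 2L, max))
}

#' Compare two phase-lock curves
#'
#' @param curveA,curveB \linkS4class{PhaseLockCurve} objects on identical
#'   frequency grids (e.g. control vs treated, or weak vs strong drive)
#' @return list with \code{table} (data.frame: frequency, responseA,
#'   responseB, ratio = B/A, \code{NA} where A = 0) and
#'   \code{bandMedianRatio} (median of the defined ratios)
#' @examples
#' a <- new("PhaseLockCurve", frequencies = c(1, 2), response = c(2, 4),
#'          amplitudeLabel = 50, dispersionLow = numeric(0),
#'          dispersionHigh = numeric(0))
#' compareCurves(a, a)$bandMedianRatio   # 1
#' @export
compareCurves <- function(curveA, curveB) {
  stopifnot(is(curveA, "PhaseLockCurve"), is(curveB, "PhaseLockCurve"))
  if (!isTRUE(all.equal(curveA@frequencies, curveB@frequencies)))
    stop("frequency grids differ between curves")
  ratio <- ifelse(curveA@response == 0, NA_real_,
                  curveB@response / curveA@response)
  list(
    table = data.frame(frequency_hz = curveA@frequencies,
                       responseA = curveA@response,
                       responseB = curveB@response, ratio = ratio),
    bandMedianRatio = stats::median(ratio, na.rm = TRUE))
}
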