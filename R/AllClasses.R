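#' @include AllGenerics.R
NULL

.TRACE_KINDS <- c("displacement_nm", "delta_i_over_i", "stimulus_nm")
.ROI_LABELS  <- c("hotspot", "control", "bundle", "background")

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' ImageStack: a time-ordered stack of 2D intensity frames
#'
#' Holds a high-speed recording as an integer-count array indexed
#' \code{[row, col, frame]}, together with the acquisition metadata the
#' downstream analysis needs (frame rate, pixel pitch, axial section index,
#' camera bit depth).
#'
#' @slot frames integer (or numeric) array \code{[row, col, frame]}, raw
#'   camera counts
#' @slot frameRate acquisition rate in Hz
#' @slot pixelPitch physical pixel size in nm/px
#' @slot zIndex axial section index (0-based; \code{NA} when not part of a
#'   z-stack)
#' @slot bitDepth camera bit depth (8 or 16)
#' @slot source provenance string (file path or simulator tag)
#' @export
setClass("ImageStack",
  representation(
    frames     = "array",
    frameRate  = "numeric",
    pixelPitch = "numeric",
    zIndex     = "integer",
    bitDepth   = "integer",
    source     = "character"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("frames must be a 3D array [row, col, frame]")
  if (d[3L] < 2L)
    return("an ImageStack needs at least 2 frames")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    return("frameRate must be a single positive number (Hz)")
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    return("pixelPitch must be a single positive number (nm/px)")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  rng <- range(object@frames)
  if (!all(is.finite(rng)) || rng[1L] < 0)
    return("counts must be finite and non-negative")
  if (rng[2L] >= 2^object@bitDepth)
    return(sprintf("counts must be < 2^%d", object@bitDepth))
  TRUE
})

#' Construct an ImageStack
#'
#' @param frames 3D array \code{[row, col, frame]} of non-negative counts
#' @param frameRate acquisition rate (Hz)
#' @param pixelPitch pixel size (nm/px); default 108.3
#' @param zIndex axial section index (0-based) or \code{NA}
#' @param bitDepth camera bit depth, 8 or 16
#' @param source provenance string
#' @return an \linkS4class{ImageStack}
#' @examples
#' st <- ImageStack(array(100L, c(4, 4, 3)), frameRate = 1000)
#' nFrames(st)
#' @export
ImageStack <- function(frames, frameRate, pixelPitch = 108.3,
                       zIndex = NA_integer_, bitDepth = 16L, source = "") {
  new("ImageStack", frames = frames, frameRate = as.numeric(frameRate),
      pixelPitch = as.numeric(pixelPitch), zIndex = as.integer(zIndex),
      bitDepth = as.integer(bitDepth), source = source)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ImageStack: %d x %d px, %d frames @ %g fps, %g nm/px, %d-bit%s\n",
    d[1L], d[2L], d[3L], object@frameRate, object@pixelPitch,
    object@bitDepth,
    if (is.na(object@zIndex)) "" else sprintf(", z = %d", object@zIndex)))
})

#' Trace: a uniformly sampled 1D time series
#'
#' Either a bundle displacement (nm), a normalized intensity fluctuation
#' (delta-I over I, dimensionless), or a stimulus command (nm).
#'
#' @slot values numeric vector of samples
#' @slot sampleRate sampling rate in Hz
#' @slot kind one of \code{"displacement_nm"}, \code{"delta_i_over_i"},
#'   \code{"stimulus_nm"}
#' @slot t0 time of the first sample (s)
#' @export
setClass("Trace",
  representation(
    values     = "numeric",
    sampleRate = "numeric",
    kind       = "character",
    t0         = "numeric"
  )
)

setValidity("Trace", function(object) {
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    return("sampleRate must be a single positive number (Hz)")
  if (!all(is.finite(object@values)))
    return("trace values must be finite")
  if (length(object@kind) != 1L || !object@kind %in% .TRACE_KINDS)
    return(paste("kind must be one of:", paste(.TRACE_KINDS, collapse = ", ")))
  TRUE
})

#' Construct a Trace
#'
#' @param values numeric samples
#' @param sampleRate sampling rate (Hz)
#' @param kind sample kind; see \linkS4class{Trace}
#' @param t0 time of first sample (s)
#' @return a \linkS4class{Trace}
#' @examples
#' tr <- Trace(sin(2 * pi * 10 * (0:999) / 1000), 1000, "displacement_nm")
#' sampleRate(tr)
#' @export
Trace <- function(values, sampleRate, kind = "displacement_nm", t0 = 0) {
  new("Trace", values = as.numeric(values), sampleRate = as.numeric(sampleRate),
      kind = kind, t0 = as.numeric(t0))
}

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace (%s): %d samples @ %g Hz, t0 = %g s\n",
              object@kind, length(object@values), object@sampleRate,
              object@t0))
})

setMethod("length", "Trace", function(x) length(x@values))

#' ActivityMap: per-pixel temporal mean and SD of a recording
#'
#' The activity heatmap: \code{sigma[r, c]} is the temporal standard
#' deviation (population normalization, 1/N) of pixel \code{(r, c)} over the
#' recording, \code{mu[r, c]} its temporal mean. \code{mask} marks the
#' analysis region the summary statistics (and hotspot detection) are
#' restricted to; \code{normalized} records whether frames were divided by
#' the per-frame spatial background mean before the statistics were taken.
#'
#' @slot mu temporal mean matrix
#' @slot sigma temporal SD matrix
#' @slot mask logical analysis-region matrix
#' @slot normalized logical flag
#' @export
setClass("ActivityMap",
  representation(
    mu         = "matrix",
    sigma      = "matrix",
    mask       = "matrix",
    normalized = "logical"
  )
)

setValidity("ActivityMap", function(object) {
  if (!identical(dim(object@mu), dim(object@sigma)) ||
      !identical(dim(object@mu), dim(object@mask)))
    return("mu, sigma and mask must share the same dimensions")
  if (any(object@sigma < 0)) return("sigma must be non-negative")
  if (any(object@mu < 0)) return("mu must be non-negative")
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

setMethod("show", "ActivityMap", function(object) {
  cat(sprintf(
    "ActivityMap: %d x %d px (%s frames), mask covers %d px, peak sigma %.4g\n",
    nrow(object@sigma), ncol(object@sigma),
    if (object@normalized) "background-normalized" else "raw",
    sum(object@mask), max(object@sigma)))
})

#' Roi: a labeled circular region of interest
#'
#' @slot center numeric \code{(row, col)} in px (0-based, sub-pixel allowed)
#' @slot radius disk radius in px
#' @slot label one of \code{"hotspot"}, \code{"control"}, \code{"bundle"},
#'   \code{"background"}
#' @slot zIndex axial section the ROI belongs to (0-based, \code{NA} allowed)
#' @export
setClass("Roi",
  representation(
    center = "numeric",
    radius = "numeric",
    label  = "character",
    zIndex = "integer"
  )
)

setValidity("Roi", function(object) {
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    return("center must be a finite (row, col) pair")
  if (length(object@radius) != 1L || object@radius < 1)
    return("radius must be >= 1 px")
  if (!object@label %in% .ROI_LABELS)
    return(paste("label must be one of:", paste(.ROI_LABELS, collapse = ", ")))
  TRUE
})

#' Construct a Roi
#'
#' @param center \code{(row, col)} center in px (0-based)
#' @param radius disk radius in px (>= 1)
#' @param label ROI label; see \linkS4class{Roi}
#' @param zIndex axial section index
#' @return a \linkS4class{Roi}
#' @examples
#' Roi(c(20, 30), radius = 5, label = "hotspot")
#' @export
Roi <- function(center, radius, label = "hotspot", zIndex = NA_integer_) {
  new("Roi", center = as.numeric(center), radius = as.numeric(radius),
      label = label, zIndex = as.integer(zIndex))
}

setMethod("show", "Roi", function(object) {
  cat(sprintf("Roi [%s]: center (%.2f, %.2f), radius %g px%s\n",
              object@label, object@center[1L], object@center[2L],
              object@radius,
              if (is.na(object@zIndex)) "" else
                sprintf(", z = %d", object@zIndex)))
})

#' Hotspot: a detected activity hotspot
#'
#' @slot roi the \linkS4class{Roi} placed at the hotspot centroid
#' @slot peakSigma maximum of the sigma map inside the component
#' @slot areaPx number of supra-threshold pixels in the component
#' @slot centroid sigma-weighted sub-pixel centroid \code{(row, col)}
#' @export
setClass("Hotspot",
  representation(
    roi       = "Roi",
    peakSigma = "numeric",
    areaPx    = "integer",
    centroid  = "numeric"
  )
)

setMethod("show", "Hotspot", function(object) {
  cat(sprintf(
    "Hotspot: centroid (%.2f, %.2f), peak sigma %.4g, area %d px\n",
    object@centroid[1L], object@centroid[2L], object@peakSigma,
    object@areaPx))
})

#' Spectrum: one-sided amplitude spectrum of a trace
#'
#' Amplitude convention: a pure sinusoid of amplitude A at an on-bin
#' frequency yields spectral amplitude A at that bin (factor 2|X(f)|/M).
#'
#' @slot frequencies Hz, increasing from 0 to Nyquist
#' @slot amplitudes amplitude per bin (input units, or peak-normalized)
#' @slot normalization \code{"none"} or \code{"max"}
#' @slot sampleRate Hz of the source trace
#' @export
setClass("Spectrum",
  representation(
    frequencies   = "numeric",
    amplitudes    = "numeric",
    normalization = "character",
    sampleRate    = "numeric"
  )
)

setValidity("Spectrum", function(object) {
  if (length(object@frequencies) != length(object@amplitudes))
    return("frequencies and amplitudes must have equal length")
  if (is.unsorted(object@frequencies, strictly = TRUE))
    return("frequencies must be strictly increasing")
  if (any(object@amplitudes < 0)) return("amplitudes must be non-negative")
  if (object@normalization == "max" &&
      abs(max(object@amplitudes) - 1) > 1e-9)
    return("a max-normalized spectrum must peak at exactly 1")
  TRUE
})

setMethod("show", "Spectrum", function(object) {
  i <- which.max(object@amplitudes)
  cat(sprintf("Spectrum: %d bins, 0-%.6g Hz, peak %.4g at %.6g Hz (%s)\n",
              length(object@frequencies), max(object@frequencies),
              object@amplitudes[i], object@frequencies[i],
              object@normalization))
})

#' CorrelationResult: maximum lagged Pearson correlation of two traces
#'
#' @slot maxCorr the maximal Pearson coefficient over the lag scan
#' @slot lag the lag (in samples, signed) at which it occurs; positive lag
#'   means the second trace is delayed relative to the first
#' @slot threshold classification threshold used
#' @slot correlated \code{maxCorr >= threshold}
#' @slot lagSeconds the lag converted to seconds
#' @export
setClass("CorrelationResult",
  representation(
    maxCorr    = "numeric",
    lag        = "integer",
    threshold  = "numeric",
    correlated = "logical",
    lagSeconds = "numeric"
  )
)

setValidity("CorrelationResult", function(object) {
  if (abs(object@maxCorr) > 1 + 1e-12) return("|maxCorr| must be <= 1")
  if (!identical(object@correlated, object@maxCorr >= object@threshold))
    return("correlated must equal maxCorr >= threshold")
  TRUE
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf(
    "CorrelationResult: max corr %.4f at lag %d samples (%.4g s); %s (threshold %.2f)\n",
    object@maxCorr, object@lag, object@lagSeconds,
    if (object@correlated) "correlated" else "not correlated",
    object@threshold))
})

#' SweepSegmentation: per-step segmentation of a frequency-sweep recording
#'
#' Segments are closed-open sample intervals tiling the sweep: segment i
#' starts at \code{starts[i]} (1-based) and holds \code{lengths[i]} samples
#' of the stepped stimulus at \code{frequencies[i]} Hz (an integer number of
#' cycles up to one-sample rounding).
#'
#' @slot starts 1-based start sample of each segment
#' @slot lengths segment lengths in samples
#' @slot frequencies stimulus frequency per segment (Hz)
#' @slot sampleRate Hz
#' @export
setClass("SweepSegmentation",
  representation(
    starts      = "integer",
    lengths     = "integer",
    frequencies = "numeric",
    sampleRate  = "numeric"
  )
)

setValidity("SweepSegmentation", function(object) {
  n <- length(object@starts)
  if (length(object@lengths) != n || length(object@frequencies) != n)
    return("starts, lengths and frequencies must have equal length")
  if (n && is.unsorted(object@starts, strictly = TRUE))
    return("starts must be strictly increasing")
  if (any(object@lengths < 16L))
    return("every segment must hold at least 16 samples")
  if (n && !all(object@starts[-1L] ==
                (object@starts[-n] + object@lengths[-n])))
    return("segments must tile the sweep without gaps or overlap")
  TRUE
})

setMethod("show", "SweepSegmentation", function(object) {
  cat(sprintf(
    "SweepSegmentation: %d steps, %.3g-%.3g Hz, %d samples total @ %g Hz\n",
    length(object@starts), min(object@frequencies), max(object@frequencies),
    sum(object@lengths), object@sampleRate))
})

#' PhaseLockCurve: per-frequency phase-locked response of a trace
#'
#' @slot frequencies stimulus frequencies (Hz)
#' @slot response phase-locked amplitude per step, in trace units
#' @slot amplitudeLabel stimulus amplitude the curve was measured at (nm)
#' @slot dispersionLow,dispersionHigh optional min-max envelope across
#'   repeats (length 0 when a single sweep was analyzed)
#' @export
setClass("PhaseLockCurve",
  representation(
    frequencies    = "numeric",
    response       = "numeric",
    amplitudeLabel = "numeric",
    dispersionLow  = "numeric",
    dispersionHigh = "numeric"
  )
)

setValidity("PhaseLockCurve", function(object) {
  if (length(object@frequencies) != length(object@response))
    return("frequencies and response must have equal length")
  if (any(object@response < 0)) return("response must be non-negative")
  if (length(object@dispersionLow) != length(object@dispersionHigh))
    return("dispersion envelopes must have equal length")
  if (length(object@dispersionLow) &&
      length(object@dispersionLow) != length(object@frequencies))
    return("dispersion envelope must match the frequency grid")
  TRUE
})

setMethod("show", "PhaseLockCurve", function(object) {
  cat(sprintf(
    "PhaseLockCurve: %d steps, %.3g-%.3g Hz, peak response %.4g%s\n",
    length(object@frequencies), min(object@frequencies),
    max(object@frequencies), max(object@response),
    if (is.na(object@amplitudeLabel)) "" else
      sprintf(" (drive %g nm)", object@amplitudeLabel)))
})

## ---------------------------------------------------------------------------
## Simulator parameter objects
## ---------------------------------------------------------------------------

#' CameraModel: acquisition parameters of the simulated camera
#'
#' Defaults follow a high-speed sCMOS recording: 1000 frames/s, 108.3 nm/px,
#' 16-bit, conversion gain 0.46 electrons per count.
#'
#' @slot frameRate Hz
#' @slot pixelPitch nm/px
#' @slot bitDepth 8 or 16
#' @slot gain electrons per count (sets the shot-noise scale)
#' @slot readNoiseSd read noise SD in counts
#' @slot frameCount number of frames to record (\code{NA} = derive from the
#'   stimulus protocol duration)
#' @export
setClass("CameraModel",
  representation(
    frameRate   = "numeric",
    pixelPitch  = "numeric",
    bitDepth    = "integer",
    gain        = "numeric",
    readNoiseSd = "numeric",
    frameCount  = "integer"
  )
)

setValidity("CameraModel", function(object) {
  if (object@frameRate <= 0) return("frameRate must be > 0")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  if (object@gain <= 0) return("gain must be > 0")
  if (object@readNoiseSd < 0) return("readNoiseSd must be >= 0")
  if (!is.na(object@frameCount) && object@frameCount < 2L)
    return("frameCount must be >= 2")
  TRUE
})

#' @param frameRate,pixelPitch,bitDepth,gain,readNoiseSd,frameCount see slots
#' @return a \linkS4class{CameraModel}
#' @rdname CameraModel-class
#' @examples
#' CameraModel()
#' @export
CameraModel <- function(frameRate = 1000, pixelPitch = 108.3, bitDepth = 16L,
                        gain = 0.46, readNoiseSd = 1.6,
                        frameCount = NA_integer_) {
  new("CameraModel", frameRate = as.numeric(frameRate),
      pixelPitch = as.numeric(pixelPitch), bitDepth = as.integer(bitDepth),
      gain = as.numeric(gain), readNoiseSd = as.numeric(readNoiseSd),
      frameCount = as.integer(frameCount))
}

setMethod("show", "CameraModel", function(object) {
  cat(sprintf(
    "CameraModel: %g fps, %g nm/px, %d-bit, gain %g e-/count, read noise %g\n",
    object@frameRate, object@pixelPitch, object@bitDepth, object@gain,
    object@readNoiseSd))
})

#' BundleModel: spontaneous and driven hair-bundle dynamics
#'
#' The spontaneous waveform is a two-state relaxation oscillation with
#' gamma-jittered dwell times (coefficient of variation
#' \code{dwellNoiseCv}), low-pass smoothed over ~2 ms, plus additive
#' Gaussian position noise; a pure sinusoid mode is provided for analytic
#' tests. A stimulus whose amplitude reaches \code{entrainmentThreshold}
#' entrains the bundle (it follows the stimulus waveform plus position
#' noise); weaker stimuli leave the spontaneous dynamics in place, but an
#' attached probe mechanically loads the bundle and scales the spontaneous
#' limit cycle by \code{probeLoadFactor}.
#'
#' @slot naturalFrequency spontaneous oscillation frequency (Hz)
#' @slot amplitude spontaneous half peak-to-peak amplitude (nm)
#' @slot waveform \code{"relaxation"} or \code{"sinusoid"}
#' @slot dutyCycle fraction of each cycle spent in the upper state
#' @slot dwellNoiseCv coefficient of variation of the dwell times
#' @slot positionNoiseSd additive Gaussian position noise SD (nm)
#' @slot entrainmentThreshold minimum stimulus amplitude that entrains (nm)
#' @slot probeLoadFactor spontaneous-amplitude scale while a probe is
#'   attached (dimensionless, in (0, 1])
#' @slot smoothingTau low-pass smoothing scale for the relaxation edges (s)
#' @export
setClass("BundleModel",
  representation(
    naturalFrequency     = "numeric",
    amplitude            = "numeric",
    waveform             = "character",
    dutyCycle            = "numeric",
    dwellNoiseCv         = "numeric",
    positionNoiseSd      = "numeric",
    entrainmentThreshold = "numeric",
    probeLoadFactor      = "numeric",
    smoothingTau         = "numeric"
  )
)

setValidity("BundleModel", function(object) {
  if (object@naturalFrequency <= 0) return("naturalFrequency must be > 0")
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (!object@waveform %in% c("relaxation", "sinusoid"))
    return("waveform must be 'relaxation' or 'sinusoid'")
  if (object@dutyCycle <= 0 || object@dutyCycle >= 1)
    return("dutyCycle must lie in (0, 1)")
  if (object@dwellNoiseCv < 0) return("dwellNoiseCv must be >= 0")
  if (object@positionNoiseSd < 0) return("positionNoiseSd must be >= 0")
  if (object@entrainmentThreshold < 0)
    return("entrainmentThreshold must be >= 0")
  if (object@probeLoadFactor <= 0 || object@probeLoadFactor > 1)
    return("probeLoadFactor must lie in (0, 1]")
  if (object@smoothingTau < 0) return("smoothingTau must be >= 0")
  TRUE
})

#' @param naturalFrequency,amplitude,waveform,dutyCycle,dwellNoiseCv see slots
#' @param positionNoiseSd,entrainmentThreshold,probeLoadFactor,smoothingTau
#'   see slots
#' @return a \linkS4class{BundleModel}
#' @rdname BundleModel-class
#' @examples
#' BundleModel(naturalFrequency = 8, amplitude = 20)
#' @export
BundleModel <- function(naturalFrequency = 8, amplitude = 20,
                        waveform = "relaxation", dutyCycle = 0.5,
                        dwellNoiseCv = 0.5, positionNoiseSd = 3,
                        entrainmentThreshold = 25, probeLoadFactor = 0.5,
                        smoothingTau = 0.002) {
  new("BundleModel", naturalFrequency = as.numeric(naturalFrequency),
      amplitude = as.numeric(amplitude), waveform = waveform,
      dutyCycle = as.numeric(dutyCycle),
      dwellNoiseCv = as.numeric(dwellNoiseCv),
      positionNoiseSd = as.numeric(positionNoiseSd),
      entrainmentThreshold = as.numeric(entrainmentThreshold),
      probeLoadFactor = as.numeric(probeLoadFactor),
      smoothingTau = as.numeric(smoothingTau))
}

setMethod("show", "BundleModel", function(object) {
  cat(sprintf(
    "BundleModel: %s, f0 %g Hz, amplitude %g nm, dwell cv %g, noise %g nm\n",
    object@waveform, object@naturalFrequency, object@amplitude,
    object@dwellNoiseCv, object@positionNoiseSd))
})

#' HotspotSpec: a simulated somatic activity hotspot
#'
#' The hotspot modulates local image intensity coherently with (lagged)
#' bundle displacement: its delta-I over I trace is
#' \code{suppressionFactor * (gain * x(t - lag) + intrinsic noise)}.
#' Rendered as an isotropic Gaussian blob (SD = radiusPx / 2) scaled by the
#' scene background level and the per-section depth attenuation.
#'
#' @slot center \code{(row, col)} blob center in px (0-based)
#' @slot radiusPx blob radius scale in px
#' @slot zIndex axial section the hotspot lives in (0..5)
#' @slot gain delta-I over I per nm of bundle displacement
#' @slot lag modulation delay relative to the bundle (s)
#' @slot intrinsicNoiseSd additive intrinsic modulation noise (delta-I/I)
#' @slot suppressionFactor 1 = healthy, 0 = fully suppressed (tip links cut)
#' @export
setClass("HotspotSpec",
  representation(
    center            = "numeric",
    radiusPx          = "numeric",
    zIndex            = "integer",
    gain              = "numeric",
    lag               = "numeric",
    intrinsicNoiseSd  = "numeric",
    suppressionFactor = "numeric"
  )
)

setValidity("HotspotSpec", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (object@radiusPx < 1) return("radiusPx must be >= 1")
  if (object@zIndex < 0L || object@zIndex > 5L)
    return("zIndex must lie in 0..5")
  if (object@suppressionFactor < 0 || object@suppressionFactor > 1)
    return("suppressionFactor must lie in [0, 1]")
  if (object@intrinsicNoiseSd < 0) return("intrinsicNoiseSd must be >= 0")
  TRUE
})

#' @param center,radiusPx,zIndex,gain,lag,intrinsicNoiseSd,suppressionFactor
#'   see slots
#' @return a \linkS4class{HotspotSpec}
#' @rdname HotspotSpec-class
#' @examples
#' HotspotSpec(center = c(40, 40), zIndex = 0L)
#' @export
HotspotSpec <- function(center, radiusPx = 5, zIndex = 0L, gain = 0.002,
                        lag = 0, intrinsicNoiseSd = 0.005,
                        suppressionFactor = 1) {
  new("HotspotSpec", center = as.numeric(center),
      radiusPx = as.numeric(radiusPx), zIndex = as.integer(zIndex),
      gain = as.numeric(gain), lag = as.numeric(lag),
      intrinsicNoiseSd = as.numeric(intrinsicNoiseSd),
      suppressionFactor = as.numeric(suppressionFactor))
}

#' StimulusProtocol: mechanical stimulation of the hair bundle
#'
#' Either no stimulus, a pure tone, or a stepped frequency sweep in which
#' each step holds an integer number of stimulus cycles.
#'
#' @slot kind \code{"none"}, \code{"pure_tone"} or \code{"sweep"}
#' @slot amplitude probe-tip displacement amplitude (nm)
#' @slot toneFrequency pure-tone frequency (Hz)
#' @slot sweepStart,sweepEnd sweep frequency range (Hz)
#' @slot cyclesPerStep stimulus cycles held per sweep step
#' @slot stepSpacing \code{"log"} or \code{"linear"}
#' @slot nSteps number of sweep steps
#' @slot duration recording duration for \code{none}/\code{pure_tone} (s);
#'   a sweep's duration is the sum of its step lengths
#' @export
setClass("StimulusProtocol",
  representation(
    kind          = "character",
    amplitude     = "numeric",
    toneFrequency = "numeric",
    sweepStart    = "numeric",
    sweepEnd      = "numeric",
    cyclesPerStep = "integer",
    stepSpacing   = "character",
    nSteps        = "integer",
    duration      = "numeric"
  )
)

setValidity("StimulusProtocol", function(object) {
  if (!object@kind %in% c("none", "pure_tone", "sweep"))
    return("kind must be 'none', 'pure_tone' or 'sweep'")
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (object@kind != "sweep" && object@duration <= 0)
    return("duration must be > 0")
  if (object@kind == "pure_tone" && object@toneFrequency <= 0)
    return("toneFrequency must be > 0")
  if (object@kind == "sweep") {
    if (object@sweepStart <= 0 || object@sweepStart >= object@sweepEnd)
      return("sweep requires 0 < sweepStart < sweepEnd")
    if (object@cyclesPerStep < 1L) return("cyclesPerStep must be >= 1")
    if (object@nSteps < 2L) return("a sweep needs at least 2 steps")
    if (!object@stepSpacing %in% c("log", "linear"))
      return("stepSpacing must be 'log' or 'linear'")
  }
  TRUE
})

#' @param kind,amplitude,toneFrequency,sweepStart,sweepEnd see slots
#' @param cyclesPerStep,stepSpacing,nSteps,duration see slots
#' @return a \linkS4class{StimulusProtocol}
#' @rdname StimulusProtocol-class
#' @examples
#' StimulusProtocol("pure_tone", amplitude = 60, toneFrequency = 10,
#'                  duration = 5)
#' @export
StimulusProtocol <- function(kind = "none", amplitude = 0, toneFrequency = 10,
                             sweepStart = 1, sweepEnd = 100,
                             cyclesPerStep = 10L, stepSpacing = "log",
                             nSteps = 30L, duration = 5) {
  new("StimulusProtocol", kind = kind, amplitude = as.numeric(amplitude),
      toneFrequency = as.numeric(toneFrequency),
      sweepStart = as.numeric(sweepStart), sweepEnd = as.numeric(sweepEnd),
      cyclesPerStep = as.integer(cyclesPerStep), stepSpacing = stepSpacing,
      nSteps = as.integer(nSteps), duration = as.numeric(duration))
}

setMethod("show", "StimulusProtocol", function(object) {
  cat(switch(object@kind,
    none = "StimulusProtocol: none (spontaneous recording)\n",
    pure_tone = sprintf(
      "StimulusProtocol: pure tone %g Hz, %g nm, %g s\n",
      object@toneFrequency, object@amplitude, object@duration),
    sweep = sprintf(
      "StimulusProtocol: %s sweep %g-%g Hz, %d steps x %d cycles, %g nm\n",
      object@stepSpacing, object@sweepStart, object@sweepEnd, object@nSteps,
      object@cyclesPerStep, object@amplitude)))
})

#' SceneSpec: static geometry of the simulated field of view
#'
#' @slot imageShape \code{(rows, cols)} in px
#' @slot somaOutline closed polygon (n x 2 matrix of 0-based \code{row, col})
#'   outlining the cell body
#' @slot bundleRoi rectangle \code{c(row0, row1, col0, col1)} (0-based,
#'   inclusive) containing the bundle ridge
#' @slot bundleAxis unit 2-vector, direction of bundle motion
#' @slot backgroundLevel mean background intensity (counts)
#' @slot somaContrast soma interior intensity relative to background
#' @slot bundleContrast ridge peak intensity relative to background
#' @slot ridgeSigmaPx Gaussian cross-section SD of the ridge (px)
#' @slot hotspots list of \linkS4class{HotspotSpec}
#' @slot zAttenuation 6-vector of per-section multiplicative gains in (0, 1]
#' @slot seed default RNG seed for renders of this scene
#' @export
setClass("SceneSpec",
  representation(
    imageShape      = "integer",
    somaOutline     = "matrix",
    bundleRoi       = "numeric",
    bundleAxis      = "numeric",
    backgroundLevel = "numeric",
    somaContrast    = "numeric",
    bundleContrast  = "numeric",
    ridgeSigmaPx    = "numeric",
    hotspots        = "list",
    zAttenuation    = "numeric",
    seed            = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    return("imageShape must be (rows, cols), each >= 8")
  if (ncol(object@somaOutline) != 2L || nrow(object@somaOutline) < 3L)
    return("somaOutline must be an n x 2 polygon with n >= 3")
  if (length(object@bundleRoi) != 4L)
    return("bundleRoi must be c(row0, row1, col0, col1)")
  if (abs(sqrt(sum(object@bundleAxis^2)) - 1) > 1e-8)
    return("bundleAxis must be a unit vector")
  if (object@backgroundLevel <= 0) return("backgroundLevel must be > 0")
  if (length(object@zAttenuation) != 6L ||
      any(object@zAttenuation <= 0) || any(object@zAttenuation > 1))
    return("zAttenuation must be a 6-vector with entries in (0, 1]")
  for (h in object@hotspots) {
    if (!is(h, "HotspotSpec")) return("hotspots must be HotspotSpec objects")
    if (any(h@center < 0) || h@center[1L] > object@imageShape[1L] - 1L ||
        h@center[2L] > object@imageShape[2L] - 1L)
      return("all hotspot centers must lie inside the image")
  }
  TRUE
})

#' @param imageShape,somaOutline,bundleRoi,bundleAxis,backgroundLevel see slots
#' @param somaContrast,bundleContrast,ridgeSigmaPx,hotspots,zAttenuation,seed
#'   see slots
#' @return a \linkS4class{SceneSpec}
#' @rdname SceneSpec-class
#' @examples
#' sc <- demoScene()
#' length(sc@hotspots)
#' @export
SceneSpec <- function(imageShape, somaOutline, bundleRoi,
                      bundleAxis = c(0, 1), backgroundLevel = 800,
                      somaContrast = 1.15, bundleContrast = 0.8,
                      ridgeSigmaPx = 2, hotspots = list(),
                      zAttenuation = exp(-(0:5) / 2.5), seed = 1L) {
  new("SceneSpec", imageShape = as.integer(imageShape),
      somaOutline = somaOutline, bundleRoi = as.numeric(bundleRoi),
      bundleAxis = as.numeric(bundleAxis),
      backgroundLevel = as.numeric(backgroundLevel),
      somaContrast = as.numeric(somaContrast),
      bundleContrast = as.numeric(bundleContrast),
      ridgeSigmaPx = as.numeric(ridgeSigmaPx), hotspots = hotspots,
      zAttenuation = as.numeric(zAttenuation), seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px, background %g counts, %d hotspot(s), seed %d\n",
    object@imageShape[1L], object@imageShape[2L], object@backgroundLevel,
    length(object@hotspots), object@seed))
})

#' GroundTruth: the generative signals behind a synthetic recording
#'
#' @slot bundleTrace bundle displacement (nm)
#' @slot hotspotTraces list of per-hotspot delta-I over I modulation traces
#'   (gain, lag, suppression and intrinsic noise already applied)
#' @slot stimulusTrace stimulus command (nm)
#' @slot stepStarts 1-based start samples of sweep steps (empty otherwise)
#' @export
setClass("GroundTruth",
  representation(
    bundleTrace   = "Trace",
    hotspotTraces = "list",
    stimulusTrace = "Trace",
    stepStarts    = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  n <- length(object@bundleTrace@values)
  if (length(object@stimulusTrace@values) != n)
    return("stimulus trace must match the bundle trace length")
  for (tr in object@hotspotTraces) {
    if (!is(tr, "Trace")) return("hotspotTraces must contain Trace objects")
    if (length(tr@values) != n)
      return("all hotspot traces must match the bundle trace length")
  }
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d samples, %d hotspot modulation trace(s)%s\n",
    length(object@bundleTrace@values), length(object@hotspotTraces),
    if (length(object@stepStarts))
      sprintf(", %d sweep steps", length(object@stepStarts)) else ""))
})

#' TrackerConfig: configuration of the sub-pixel bundle tracker
#'
#' @slot roi \linkS4class{Roi} (label \code{"bundle"}) covering the ridge
#' @slot axis unit 2-vector: motion direction the position is projected on
#' @slot method \code{"centroid"} (floor-subtracted intensity centroid) or
#'   \code{"gaussian_fit"} (least-squares 1D Gaussian refinement)
#' @slot baseline \code{"mean"} or \code{"first_frame"}
#' @export
setClass("TrackerConfig",
  representation(
    roi      = "Roi",
    axis     = "numeric",
    method   = "character",
    baseline = "character"
  )
)

setValidity("TrackerConfig", function(object) {
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    return("axis must be a unit vector")
  if (!object@method %in% c("centroid", "gaussian_fit"))
    return("method must be 'centroid' or 'gaussian_fit'")
  if (!object@baseline %in% c("mean", "first_frame"))
    return("baseline must be 'mean' or 'first_frame'")
  TRUE
})

#' @param roi,axis,method,baseline see slots
#' @return a \linkS4class{TrackerConfig}
#' @rdname TrackerConfig-class
#' @examples
#' TrackerConfig(Roi(c(10, 32), 8, label = "bundle"))
#' @export
TrackerConfig <- function(roi, axis = c(0, 1), method = "centroid",
                          baseline = "mean") {
  new("TrackerConfig", roi = roi, axis = as.numeric(axis), method = method,
      baseline = baseline)
}
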