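#' @include AllClasses.R utils.R
NULL

## ---------------------------------------------------------------------------
## Stimulus construction
## ---------------------------------------------------------------------------

.sweepFrequencies <- function(protocol) {
  switch(protocol@stepSpacing,
    log = exp(seq(log(protocol@sweepStart), log(protocol@sweepEnd),
                  length.out = protocol@nSteps)),
    linear = seq(protocol@sweepStart, protocol@sweepEnd,
                 length.out = protocol@nSteps))
}

## Realize the stimulus command at the camera frame rate. A sweep is stepped:
## each frequency is held for round(cyclesPerStep * fs / f) samples, each
## step starting at phase zero.
.makeStimulus <- function(protocol, fs) {
  if (protocol@kind == "none") {
    n <- round(protocol@duration * fs)
    return(list(values = rep(0, n), starts = integer(0),
                lengths = integer(0), frequencies = numeric(0)))
  }
  if (protocol@kind == "pure_tone") {
    n <- round(protocol@duration * fs)
    t <- (0:(n - 1)) / fs
    return(list(
      values = protocol@amplitude * sin(2 * pi * protocol@toneFrequency * t),
      starts = integer(0), lengths = integer(0), frequencies = numeric(0)))
  }
  f <- .sweepFrequencies(protocol)
  len <- as.integer(round(protocol@cyclesPerStep * fs / f))
  vals <- unlist(lapply(seq_along(f), function(i) {
    protocol@amplitude * sin(2 * pi * f[i] * (0:(len[i] - 1L)) / fs)
  }))
  starts <- as.integer(cumsum(c(1L, len[-length(len)])))
  list(values = vals, starts = starts, lengths = len, frequencies = f)
}

## ---------------------------------------------------------------------------
## Bundle dynamics
## ---------------------------------------------------------------------------

## Two-state relaxation oscillation: alternating dwells in the +A and -A
## states with gamma-distributed dwell times (mean dutyCycle/f0 up,
## (1-dutyCycle)/f0 down; coefficient of variation dwellNoiseCv), edges
## smoothed by a short Gaussian low-pass. RNG state is consumed here, so the
## caller controls the seed.
.relaxationWave <- function(n, fs, f0, amplitude, dutyCycle, cv, tau) {
  totalT <- n / fs
  meanUp <- dutyCycle / f0
  meanDown <- (1 - dutyCycle) / f0
  nDwell <- max(8L, ceiling(2.5 * totalT * f0) * 2L)
  repeat {
    up <- if (cv > 0) {
      shape <- 1 / cv^2
      stats::rgamma(nDwell, shape = shape, rate = shape / meanUp)
    } else rep(meanUp, nDwell)
    down <- if (cv > 0) {
      shape <- 1 / cv^2
      stats::rgamma(nDwell, shape = shape, rate = shape / meanDown)
    } else rep(meanDown, nDwell)
    dwell <- as.vector(rbind(up, down))
    if (sum(dwell) >= totalT) break
    nDwell <- nDwell * 2L
  }
  edges <- cumsum(dwell)
  ## state at sample t: number of completed dwells determines the sign
  tt <- (0:(n - 1)) / fs
  state <- findInterval(tt, edges)
  x <- ifelse(state %% 2L == 0L, amplitude, -amplitude)
  .gaussSmooth(x, tau * fs)
}

#' Simulate hair-bundle displacement under a stimulus protocol
#'
#' With no stimulus the bundle performs its spontaneous oscillation (noisy
#' relaxation cycle, or a pure sinusoid for analytic tests). A pure tone or
#' sweep whose amplitude reaches the model's entrainment threshold entrains
#' the bundle: the output follows the stimulus waveform plus position noise.
#' Below threshold the spontaneous dynamics persist, attenuated by the
#' probe-loading factor while the fiber is attached.
#'
#' @param model a \linkS4class{BundleModel}
#' @param protocol a \linkS4class{StimulusProtocol}
#' @param camera a \linkS4class{CameraModel} (sets the sampling rate)
#' @param seed integer RNG seed
#' @return a \linkS4class{Trace} of kind \code{"displacement_nm"} sampled at
#'   the camera frame rate
#' @examples
#' tone <- StimulusProtocol("pure_tone", amplitude = 60, toneFrequency = 10,
#'                          duration = 1)
#' bm <- BundleModel(waveform = "sinusoid", positionNoiseSd = 0)
#' tr <- simulateBundle(bm, tone)
#' length(tr)
#' @export
simulateBundle <- function(model, protocol = StimulusProtocol("none"),
                           camera = CameraModel(), seed = 1L) {
  stopifnot(is(model, "BundleModel"), is(protocol, "StimulusProtocol"),
            is(camera, "CameraModel"))
  fs <- camera@frameRate
  if (protocol@kind != "sweep" && protocol@duration <= 0)
    stop("protocol duration must be positive")
  stim <- .makeStimulus(protocol, fs)
  n <- length(stim$values)
  if (n < 2L) stop("protocol too short: fewer than 2 samples")
  set.seed(.deriveSeed(seed, 101L))
  entrained <- protocol@kind != "none" &&
    protocol@amplitude >= model@entrainmentThreshold
  if (entrained) {
    x <- stim$values
  } else {
    load <- if (protocol@kind != "none" && protocol@amplitude > 0)
      model@probeLoadFactor else 1
    a <- model@amplitude * load
    x <- switch(model@waveform,
      sinusoid = a * sin(2 * pi * model@naturalFrequency *
                           (0:(n - 1)) / fs),
      relaxation = .relaxationWave(n, fs, model@naturalFrequency, a,
                                   model@dutyCycle, model@dwellNoiseCv,
                                   model@smoothingTau))
  }
  if (model@positionNoiseSd > 0)
    x <- x + stats::rnorm(n, sd = model@positionNoiseSd)
  Trace(x, sampleRate = fs, kind = "displacement_nm")
}

## ---------------------------------------------------------------------------
## Ground truth and rendering
## ---------------------------------------------------------------------------

#' Build the ground-truth modulation traces for a scene
#'
#' Each hotspot's delta-I over I modulation is
#' \code{suppressionFactor * (gain * x(t - lag) + intrinsic noise)} where x
#' is the bundle displacement; the lag is rounded to whole samples and the
#' leading edge is padded with the first value.
#'
#' @param scene a \linkS4class{SceneSpec}
#' @param bundleTrace the bundle displacement \linkS4class{Trace} (nm)
#' @param stimulusTrace optional stimulus command trace; defaults to zeros
#' @param stepStarts 1-based sweep step starts (empty for non-sweep)
#' @param seed integer RNG seed for the intrinsic hotspot noise
#' @return a \linkS4class{GroundTruth}
#' @export
makeGroundTruth <- function(scene, bundleTrace, stimulusTrace = NULL,
                            stepStarts = integer(0), seed = 1L) {
  stopifnot(is(scene, "SceneSpec"), is(bundleTrace, "Trace"))
  x <- bundleTrace@values
  fs <- bundleTrace@sampleRate
  n <- length(x)
  if (is.null(stimulusTrace))
    stimulusTrace <- Trace(rep(0, n), fs, "stimulus_nm")
  traces <- vector("list", length(scene@hotspots))
  for (i in seq_along(scene@hotspots)) {
    h <- scene@hotspots[[i]]
    set.seed(.deriveSeed(seed, 200L + i))
    base <- h@gain * .delaySamples(x, as.integer(round(h@lag * fs)))
    noise <- if (h@intrinsicNoiseSd > 0)
      stats::rnorm(n, sd = h@intrinsicNoiseSd) else rep(0, n)
    traces[[i]] <- Trace(h@suppressionFactor * (base + noise), fs,
                         "delta_i_over_i")
  }
  new("GroundTruth", bundleTrace = bundleTrace, hotspotTraces = traces,
      stimulusTrace = stimulusTrace, stepStarts = as.integer(stepStarts))
}

#' Render one axial section of a synthetic recording
#'
#' Forward model per frame: static scene (background plus soma interior
#' contrast) + one isotropic Gaussian blob per hotspot of this z-section,
#' scaled by \code{backgroundLevel * zAttenuation[z + 1] * m_i(t)} where
#' m_i is the hotspot's ground-truth delta-I over I modulation + (at
#' z = 0) a Gaussian intensity ridge in the bundle ROI translated along the
#' bundle axis by the bundle displacement in pixels. Shot noise is Poisson
#' (Gaussian approximation with variance counts/gain above 50 counts),
#' read noise Gaussian, and the result is quantized to the camera bit depth
#' with saturation clipping.
#'
#' @param scene a \linkS4class{SceneSpec}
#' @param truth a \linkS4class{GroundTruth} matching the camera frame count
#' @param camera a \linkS4class{CameraModel}
#' @param zIndex axial section to render (0-based, 0..5)
#' @param noise logical; FALSE renders the noiseless forward model
#' @param seed integer RNG seed for the camera noise
#' @return an \linkS4class{ImageStack}
#' @examples
#' sc <- demoScene(shape = c(32, 32))
#' bm <- BundleModel(waveform = "sinusoid", amplitude = 20,
#'                   positionNoiseSd = 0)
#' tr <- simulateBundle(bm, StimulusProtocol("none", duration = 0.1))
#' truth <- makeGroundTruth(sc, tr)
#' st <- renderStack(sc, truth, CameraModel(), zIndex = 0L, noise = FALSE)
#' @export
renderStack <- function(scene, truth, camera, zIndex = 0L, noise = TRUE,
                        seed = scene@seed) {
  stopifnot(is(scene, "SceneSpec"), is(truth, "GroundTruth"),
            is(camera, "CameraModel"))
  zIndex <- as.integer(zIndex)
  if (zIndex < 0L || zIndex > 5L) stop("zIndex must lie in 0..5")
  n <- length(truth@bundleTrace@values)
  if (!is.na(camera@frameCount) && camera@frameCount != n)
    stop("ground-truth traces do not match camera frameCount")
  shape <- scene@imageShape
  npix <- prod(shape)

  ## static scene
  soma <- .polygonMask(shape, scene@somaOutline)
  bg <- matrix(scene@backgroundLevel, shape[1L], shape[2L])
  bg[soma] <- scene@backgroundLevel * scene@somaContrast
  static <- as.numeric(bg)

  ## hotspot blob bases for this section
  here <- Filter(function(h) h@zIndex == zIndex, scene@hotspots)
  zg <- scene@zAttenuation[zIndex + 1L]
  blobs <- NULL
  amps <- NULL
  if (length(here)) {
    idxHere <- which(vapply(scene@hotspots,
                            function(h) h@zIndex == zIndex, logical(1L)))
    blobs <- matrix(0, npix, length(here))
    amps <- matrix(0, length(here), n)
    rr <- matrix(0:(shape[1L] - 1L), shape[1L], shape[2L])
    cc <- matrix(0:(shape[2L] - 1L), shape[1L], shape[2L], byrow = TRUE)
    for (j in seq_along(here)) {
      h <- here[[j]]
      ext <- 2 * h@radiusPx
      if (h@center[1L] - ext < 0 || h@center[2L] - ext < 0 ||
          h@center[1L] + ext > shape[1L] - 1L ||
          h@center[2L] + ext > shape[2L] - 1L)
        stop("hotspot blob extends beyond the image bounds")
      s2 <- (h@radiusPx / 2)^2
      blobs[, j] <- as.numeric(
        exp(-((rr - h@center[1L])^2 + (cc - h@center[2L])^2) / (2 * s2)))
      amps[j, ] <- scene@backgroundLevel * zg *
        truth@hotspotTraces[[idxHere[j]]]@values
    }
  }

  ## bundle ridge geometry (rendered at the stereocilia focal plane, z = 0)
  ridge <- NULL
  if (zIndex == 0L) {
    rect <- round(scene@bundleRoi)
    rows <- (rect[1L]:rect[2L]) + 1L
    cols <- (rect[3L]:rect[4L]) + 1L
    ridgeIdx <- as.integer(outer(rows, (cols - 1L) * shape[1L], "+"))
    pr <- rep(rows - 1L, times = length(cols))
    pc <- rep(cols - 1L, each = length(rows))
    proj <- pr * scene@bundleAxis[1L] + pc * scene@bundleAxis[2L]
    p0 <- mean(range(proj))
    ridge <- list(idx = ridgeIdx, proj = proj, p0 = p0,
                  amp = scene@bundleContrast * scene@backgroundLevel,
                  s2 = scene@ridgeSigmaPx^2,
                  shift = truth@bundleTrace@values / camera@pixelPitch)
  }

  maxval <- 2^camera@bitDepth - 1
  out <- array(0L, c(shape[1L], shape[2L], n))
  set.seed(.deriveSeed(seed, 300L + zIndex))
  chunk <- max(1L, min(n, as.integer(floor(8e6 / npix))))
  k0 <- 1L
  while (k0 <= n) {
    k1 <- min(n, k0 + chunk - 1L)
    kk <- k0:k1
    m <- matrix(static, npix, length(kk))
    if (!is.null(blobs))
      m <- m + blobs %*% amps[, kk, drop = FALSE]
    if (!is.null(ridge)) {
      for (ii in seq_along(kk)) {
        m[ridge$idx, ii] <- m[ridge$idx, ii] + ridge$amp *
          exp(-(ridge$proj - ridge$p0 - ridge$shift[kk[ii]])^2 /
                (2 * ridge$s2))
      }
    }
    if (noise) {
      ## shot noise: Gaussian approximation above 50 counts (variance
      ## counts/gain), exact Poisson below; read noise folded into the
      ## Gaussian draw where possible
      m[m < 0] <- 0
      g <- stats::rnorm(length(m),
                        sd = sqrt(m / camera@gain + camera@readNoiseSd^2))
      low <- m <= 50
      if (any(low))
        g[low] <- stats::rpois(sum(low), m[low] * camera@gain) /
          camera@gain - m[low] +
          stats::rnorm(sum(low), sd = camera@readNoiseSd)
      m <- m + g
    }
    m <- round(m)
    m[m < 0] <- 0
    m[m > maxval] <- maxval
    out[, , kk] <- as.integer(m)
    k0 <- k1 + 1L
  }
  ImageStack(out, frameRate = camera@frameRate,
             pixelPitch = camera@pixelPitch, zIndex = zIndex,
             bitDepth = camera@bitDepth, source = "fluctmap simulator")
}

#' Generate a complete annotated synthetic dataset
#'
#' Simulates the bundle under the given protocol, builds ground-truth
#' hotspot modulation traces, and renders one image stack per requested
#' axial section. The pharmacological condition is emulated at the level of
#' the generative model: \code{"bapta"} (tip links severed) sets every
#' hotspot's suppression factor to 0 and disables entrainment;
#' \code{"salicylate"} (prestin blocked) leaves the dynamics untouched and
#' is recorded only in the manifest. Conditions sharing a master seed share
#' all component noise streams, so control/treated pairs are matched.
#'
#' @param scene a \linkS4class{SceneSpec}
#' @param bundleModel a \linkS4class{BundleModel}
#' @param protocol a \linkS4class{StimulusProtocol}
#' @param camera a \linkS4class{CameraModel}
#' @param condition \code{"control"}, \code{"bapta"} or \code{"salicylate"}
#' @param seed master integer seed; all component streams derive from it
#' @param zIndices axial sections to render; default: section 0 plus every
#'   section holding a hotspot
#' @param noise logical; FALSE renders noiseless stacks
#' @return a list with elements \code{stacks} (named list of
#'   \linkS4class{ImageStack}, one per z), \code{truth}
#'   (\linkS4class{GroundTruth}) and \code{manifest} (parameter record)
#' @examples
#' sc <- demoScene(shape = c(32, 32))
#' ds <- makeDataset(sc, BundleModel(waveform = "sinusoid"),
#'                   StimulusProtocol("none", duration = 0.05),
#'                   CameraModel(), seed = 7L)
#' names(ds$stacks)
#' @export
makeDataset <- function(scene, bundleModel, protocol, camera,
                        condition = c("control", "bapta", "salicylate"),
                        seed = 1L, zIndices = NULL, noise = TRUE) {
  condition <- match.arg(condition)
  stopifnot(is(scene, "SceneSpec"), is(bundleModel, "BundleModel"))
  scene2 <- scene
  model2 <- bundleModel
  if (condition == "bapta") {
    model2@entrainmentThreshold <- Inf
    scene2@hotspots <- lapply(scene@hotspots, function(h) {
      h@suppressionFactor <- 0
      h
    })
  }
  bundle <- simulateBundle(model2, protocol, camera,
                           seed = .deriveSeed(seed, 1L))
  fs <- camera@frameRate
  stim <- .makeStimulus(protocol, fs)
  n <- length(bundle@values)
  truth <- makeGroundTruth(scene2, bundle,
                           Trace(stim$values, fs, "stimulus_nm"),
                           stepStarts = stim$starts,
                           seed = .deriveSeed(seed, 2L))
  camera@frameCount <- n
  if (is.null(zIndices))
    zIndices <- sort(unique(c(0L, vapply(scene@hotspots,
                                         function(h) h@zIndex, integer(1L)))))
  stacks <- lapply(zIndices, function(z)
    renderStack(scene2, truth, camera, zIndex = z, noise = noise,
                seed = .deriveSeed(seed, 50L + z)))
  names(stacks) <- paste0("z", zIndices)
  manifest <- list(
    condition = condition, seed = as.integer(seed),
    frameCount = n, frameRate = fs, pixelPitch = camera@pixelPitch,
    bitDepth = camera@bitDepth, gain = camera@gain,
    readNoiseSd = camera@readNoiseSd,
    bundle = list(waveform = model2@waveform,
                  naturalFrequency = model2@naturalFrequency,
                  amplitude = model2@amplitude,
                  dutyCycle = model2@dutyCycle,
                  dwellNoiseCv = model2@dwellNoiseCv,
                  positionNoiseSd = model2@positionNoiseSd,
                  entrainmentThreshold = model2@entrainmentThreshold,
                  probeLoadFactor = model2@probeLoadFactor),
    stimulus = list(kind = protocol@kind, amplitude = protocol@amplitude,
                    toneFrequency = protocol@toneFrequency,
                    sweepStart = protocol@sweepStart,
                    sweepEnd = protocol@sweepEnd,
                    cyclesPerStep = protocol@cyclesPerStep,
                    stepSpacing = protocol@stepSpacing,
                    nSteps = protocol@nSteps,
                    duration = protocol@duration),
    hotspots = lapply(scene2@hotspots, function(h)
      list(center = h@center, radiusPx = h@radiusPx, zIndex = h@zIndex,
           gain = h@gain, lag = h@lag,
           intrinsicNoiseSd = h@intrinsicNoiseSd,
           suppressionFactor = h@suppressionFactor)),
    zIndices = zIndices, noise = noise)
  list(stacks = stacks, truth = truth, manifest = manifest)
}

#' A ready-made demonstration scene
#'
#' Builds a scene with proportions mimicking a hair-cell field of view: a
#' roughly circular soma in the lower two thirds of the frame, a bundle
#' ridge near the top edge moving along the column axis, and one or more
#' hotspots near the soma periphery.
#'
#' @param shape \code{(rows, cols)} in px
#' @param hotspots optional list of \linkS4class{HotspotSpec}; default one
#'   healthy hotspot on the soma periphery at z = 0
#' @param backgroundLevel mean background counts
#' @param seed scene seed
#' @param ... passed through to \code{\link{SceneSpec}}
#' @return a \linkS4class{SceneSpec}
#' @examples
#' demoScene()
#' @export
demoScene <- function(shape = c(64, 64), hotspots = NULL,
                      backgroundLevel = 800, seed = 1L, ...) {
  shape <- as.integer(shape)
  ctr <- c(0.62 * shape[1L], 0.5 * shape[2L])
  rad <- 0.28 * min(shape)
  th <- seq(0, 2 * pi, length.out = 25L)[-25L]
  poly <- cbind(ctr[1L] + rad * sin(th), ctr[2L] + rad * cos(th))
  bundleRoi <- c(round(0.03 * shape[1L]), round(0.19 * shape[1L]),
                 round(0.31 * shape[2L]), round(0.69 * shape[2L]))
  if (is.null(hotspots)) {
    hr <- min(5, max(2, round(0.08 * min(shape))))
    hotspots <- list(HotspotSpec(
      center = round(c(ctr[1L], ctr[2L] - 0.75 * rad)), radiusPx = hr,
      zIndex = 0L))
  }
  SceneSpec(imageShape = shape, somaOutline = poly, bundleRoi = bundleRoi,
            bundleAxis = c(0, 1), backgroundLevel = backgroundLevel,
            hotspots = hotspots, seed = seed, ...)
}

#' Logical mask of the soma interior of a scene
#'
#' Rasterizes the scene's soma outline; pixels inside the polygon are TRUE.
#' This is the natural analysis mask for hotspot detection (it excludes the
#' bundle ridge and the extracellular background).
#'
#' @param scene a \linkS4class{SceneSpec}
#' @return logical matrix of the scene's image shape
#' @export
somaMask <- function(scene) {
  stopifnot(is(scene, "SceneSpec"))
  .polygonMask(scene@imageShape, scene@somaOutline)
}

#' A background Roi guaranteed to lie outside the demo scene's soma
#'
#' Convenience for delta-I over I extraction on simulated data: returns a
#' disk in the image corner opposite the bundle, clear of the soma polygon
#' and the bundle ROI.
#'
#' @param scene a \linkS4class{SceneSpec} built by \code{\link{demoScene}}
#' @param radius disk radius (px); default scales with the image,
#'   capped at 5
#' @return a \linkS4class{Roi} labeled \code{"background"}
#' @export
backgroundRoi <- function(scene, radius = NULL) {
  shape <- scene@imageShape
  if (is.null(radius)) radius <- min(5, max(2, round(0.08 * min(shape))))
  Roi(c(0.12 * shape[1L], 0.85 * shape[2L]), radius = radius,
      label = "background")
}
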