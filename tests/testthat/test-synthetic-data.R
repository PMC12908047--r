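test_that("an entraining pure tone reproduces the commanded sinusoid", {
  ## 10 Hz, 60 nm, 5 s at 1000 fps; 60 nm is above the entrainment
  ## threshold, so with noise off the bundle follows the drive exactly
  bm <- BundleModel(waveform = "sinusoid", positionNoiseSd = 0)
  tone <- StimulusProtocol("pure_tone", amplitude = 60, toneFrequency = 10,
                           duration = 5)
  tr <- simulateBundle(bm, tone, CameraModel(), seed = 1L)
  expect_length(traceValues(tr), 5000L)
  t <- (0:4999) / 1000
  expect_equal(traceValues(tr), 60 * sin(2 * pi * 10 * t), tolerance = 1e-12)
})

test_that("a null oscillator yields an all-zero trace", {
  for (wf in c("sinusoid", "relaxation")) {
    bm <- BundleModel(waveform = wf, amplitude = 0, positionNoiseSd = 0)
    tr <- simulateBundle(bm, StimulusProtocol("none", duration = 0.5),
                         CameraModel(), seed = 3L)
    expect_equal(traceValues(tr), rep(0, 500))
  }
})

test_that("relaxation dwell statistics follow the duty cycle", {
  ## census oracle: fraction of samples in the upper (positive) state
  bm <- BundleModel(waveform = "relaxation", dutyCycle = 0.3,
                    dwellNoiseCv = 0.3, positionNoiseSd = 0, amplitude = 25)
  tr <- simulateBundle(bm, StimulusProtocol("none", duration = 60),
                       CameraModel(), seed = 11L)
  x <- traceValues(tr)
  fracUp <- mean(x > 0)
  expect_gt(fracUp, 0.25)
  expect_lt(fracUp, 0.35)
  ## the oscillator actually alternates: both states visited many times
  transitions <- sum(diff(sign(x)) != 0)
  expect_gt(transitions, 2 * 0.5 * 60 * bm@naturalFrequency)
})

test_that("a noiseless render of a static truth repeats the scene exactly", {
  sc <- demoScene(shape = c(48, 48))
  bm <- BundleModel(waveform = "sinusoid", amplitude = 0,
                    positionNoiseSd = 0)
  tr <- simulateBundle(bm, StimulusProtocol("none", duration = 0.05))
  sc@hotspots[[1]]@intrinsicNoiseSd <- 0
  truth <- makeGroundTruth(sc, tr)
  st <- renderStack(sc, truth, CameraModel(), noise = FALSE)
  f <- frames(st)
  for (k in 2:dim(f)[3]) expect_identical(f[, , k], f[, , 1])
  ## scene structure: soma interior brighter than background
  expect_identical(f[2, 2, 1], 800L)
  inside <- which(somaMask(sc), arr.ind = TRUE)[1, ]
  expect_identical(f[inside[1], inside[2], 1], 920L)
})

test_that("hotspot temporal SD matches the closed form for a sine", {
  ## population SD of a full-cycle sampled sinusoid is amplitude / sqrt(2)
  for (z in c(0L, 2L)) {
    sc <- demoScene(shape = c(48, 48))
    h <- sc@hotspots[[1]]
    h@zIndex <- z
    h@intrinsicNoiseSd <- 0
    h@lag <- 0
    sc@hotspots <- list(h)
    bm <- BundleModel(waveform = "sinusoid", naturalFrequency = 10,
                      amplitude = 30, positionNoiseSd = 0)
    tr <- simulateBundle(bm, StimulusProtocol("none", duration = 1))
    truth <- makeGroundTruth(sc, tr)
    st <- renderStack(sc, truth, CameraModel(), zIndex = z, noise = FALSE)
    amap <- temporalStats(st, normalize = FALSE)
    expected <- h@gain * 30 * 800 * sc@zAttenuation[z + 1] / sqrt(2)
    got <- sigmaMap(amap)[h@center[1] + 1, h@center[2] + 1]
    expect_equal(got, expected, tolerance = 0.01)
  }
})

test_that("suppression scales the rendered modulation amplitude", {
  ## noiseless render difference: suppression 0.35 vs 1.0 gives a 0.35
  ## amplitude ratio at the hotspot center
  sc1 <- demoScene(shape = c(48, 48))
  sc1@hotspots[[1]]@intrinsicNoiseSd <- 0
  sc2 <- sc1
  sc2@hotspots[[1]]@suppressionFactor <- 0.35
  bm <- BundleModel(waveform = "sinusoid", naturalFrequency = 10,
                    amplitude = 30, positionNoiseSd = 0)
  tr <- simulateBundle(bm, StimulusProtocol("none", duration = 0.5))
  cam <- CameraModel()
  f1 <- frames(renderStack(sc1, makeGroundTruth(sc1, tr), cam,
                           noise = FALSE))
  f2 <- frames(renderStack(sc2, makeGroundTruth(sc2, tr), cam,
                           noise = FALSE))
  ctr <- sc1@hotspots[[1]]@center + 1
  a1 <- diff(range(f1[ctr[1], ctr[2], ]))
  a2 <- diff(range(f2[ctr[1], ctr[2], ]))
  expect_equal(a2 / a1, 0.35, tolerance = 0.02)
})

test_that("salicylate is a no-op and BAPTA silences hotspot modulation", {
  sc <- demoScene(shape = c(32, 32))
  bm <- BundleModel()
  cam <- CameraModel()
  p <- StimulusProtocol("none", duration = 0.3)
  ctl <- makeDataset(sc, bm, p, cam, "control", seed = 9L)
  sal <- makeDataset(sc, bm, p, cam, "salicylate", seed = 9L)
  expect_identical(traceValues(sal$truth@hotspotTraces[[1]]),
                   traceValues(ctl$truth@hotspotTraces[[1]]))
  expect_identical(frames(sal$stacks$z0), frames(ctl$stacks$z0))

  sweep <- StimulusProtocol("sweep", amplitude = 50, sweepStart = 20,
                            sweepEnd = 60, nSteps = 4L)
  bap <- makeDataset(sc, bm, sweep, cam, "bapta", seed = 9L)
  expect_identical(traceValues(bap$truth@hotspotTraces[[1]]),
                   rep(0, length(bap$truth@bundleTrace@values)))
})

test_that("dataset generation is bit-identical for a fixed seed", {
  sc <- demoScene(shape = c(32, 32))
  bm <- BundleModel()
  p <- StimulusProtocol("none", duration = 0.3)
  d1 <- makeDataset(sc, bm, p, CameraModel(), "control", seed = 21L)
  d2 <- makeDataset(sc, bm, p, CameraModel(), "control", seed = 21L)
  expect_identical(frames(d1$stacks$z0), frames(d2$stacks$z0))
  expect_identical(traceValues(d1$truth@bundleTrace),
                   traceValues(d2$truth@bundleTrace))
  expect_identical(d1$manifest, d2$manifest)
})

test_that("default renders stay far from saturation", {
  sc <- demoScene(shape = c(48, 48))
  bm <- BundleModel()
  ds <- makeDataset(sc, bm, StimulusProtocol("none", duration = 0.5),
                    CameraModel(), "control", seed = 2L)
  mx <- max(frames(ds$stacks$z0))
  expect_lt(mx, 2^16 - 1)
  expect_gte(mean(frames(ds$stacks$z0) < 2^16 - 1), 0.999)
})

test_that("stimuli above threshold entrain; below, spontaneity persists", {
  bm <- BundleModel(waveform = "sinusoid", naturalFrequency = 8)
  cam <- CameraModel()
  spont <- simulateBundle(bm, StimulusProtocol("none", duration = 4),
                          cam, seed = 5L)
  strong <- simulateBundle(bm,
    StimulusProtocol("pure_tone", amplitude = 50, toneFrequency = 20,
                     duration = 4), cam, seed = 5L)
  weak <- simulateBundle(bm,
    StimulusProtocol("pure_tone", amplitude = 10, toneFrequency = 20,
                     duration = 4), cam, seed = 5L)
  ampAt <- function(tr, f) {
    sp <- normalizedSpectrum(tr)
    amplitudes(sp)[which.min(abs(frequencies(sp) - f))]
  }
  ## entrainment monotonicity at the stimulus frequency
  expect_gt(ampAt(strong, 20), 5 * ampAt(spont, 20))
  ## strong drive: dominant component tracks the stimulus
  expect_equal(peakMetrics(normalizedSpectrum(strong))$peakFrequency, 20,
               tolerance = 1e-9)
  ## weak drive: dominant component remains the natural frequency
  expect_equal(peakMetrics(normalizedSpectrum(weak))$peakFrequency, 8,
               tolerance = 0.3)
})

test_that("out-of-bounds hotspot blobs are rejected at render time", {
  sc <- demoScene(shape = c(48, 48))
  sc@hotspots[[1]]@center <- c(3, 24)   # blob support would leave the frame
  bm <- BundleModel(waveform = "sinusoid")
  tr <- simulateBundle(bm, StimulusProtocol("none", duration = 0.05))
  expect_error(renderStack(sc, makeGroundTruth(sc, tr), CameraModel()),
               "beyond the image bounds")
})
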