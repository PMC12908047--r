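test_that("temporal statistics handle degenerate sequences exactly", {
  ## constant sequence: sigma = 0, mu = the frame
  fr <- matrix(sample.int(1000L, 36), 6, 6)
  st <- ImageStack(array(fr, c(6, 6, 4)), frameRate = 1000)
  amap <- temporalStats(st, normalize = FALSE)
  expect_equal(muMap(amap), fr + 0)
  expect_equal(sigmaMap(amap), matrix(0, 6, 6))

  ## two-point alternation 100/200: mu 150, sigma 50 (population SD)
  st2 <- ImageStack(array(rep(c(100L, 200L), each = 16), c(4, 4, 2)),
                    frameRate = 1000)
  amap2 <- temporalStats(st2, normalize = FALSE)
  expect_equal(muMap(amap2)[2, 3], 150)
  expect_equal(sigmaMap(amap2)[2, 3], 50)
})

test_that("temporal statistics match the double-loop oracle", {
  set.seed(101)
  for (rep in 1:4) {
    d <- c(sample(8:16, 1), sample(8:16, 1), sample(20:100, 1))
    arr <- array(sample.int(50000L, prod(d), replace = TRUE), d)
    st <- ImageStack(arr, frameRate = 1000)
    bg <- matrix(FALSE, d[1], d[2]); bg[1:3, 1:3] <- TRUE
    for (normalize in c(FALSE, TRUE)) {
      amap <- temporalStats(st, normalize = normalize,
                            background = if (normalize) bg else NULL)
      oracle <- oracleTemporalStats(arr, normalize = normalize,
                                    bgMask = if (normalize) bg else NULL)
      expect_equal(muMap(amap), oracle$mu, tolerance = 1e-10)
      expect_equal(sigmaMap(amap), oracle$sigma, tolerance = 1e-10)
    }
  }
})

test_that("temporal statistics are invariant to frame order", {
  set.seed(5)
  arr <- array(sample.int(1000L, 5 * 5 * 30, replace = TRUE), c(5, 5, 30))
  st1 <- ImageStack(arr, frameRate = 1000)
  st2 <- ImageStack(arr[, , sample(30)], frameRate = 1000)
  a1 <- temporalStats(st1, normalize = FALSE)
  a2 <- temporalStats(st2, normalize = FALSE)
  expect_equal(sigmaMap(a1), sigmaMap(a2), tolerance = 1e-12)
  expect_equal(muMap(a1), muMap(a2), tolerance = 1e-12)
})

test_that("background normalization cancels per-frame illumination", {
  set.seed(6)
  arr <- array(100 + runif(8 * 8 * 20) * 50, c(8, 8, 20))
  factors <- 1 + 0.2 * sin(seq_len(20))
  arr2 <- sweep(arr, 3, factors, "*")
  st1 <- ImageStack(arr, frameRate = 1000)
  st2 <- ImageStack(arr2, frameRate = 1000)
  bg <- matrix(FALSE, 8, 8); bg[6:8, 6:8] <- TRUE
  a1 <- temporalStats(st1, normalize = TRUE, background = bg)
  a2 <- temporalStats(st2, normalize = TRUE, background = bg)
  expect_equal(sigmaMap(a1), sigmaMap(a2), tolerance = 1e-10)
})

test_that("hotspot detection behaves on analytic sigma maps", {
  ## flat zero map: nothing to detect
  amap0 <- ActivityMap(mu = matrix(1, 32, 32), sigma = matrix(0, 32, 32))
  expect_identical(detectHotspots(amap0), list())

  ## single Gaussian bump on a flat floor: one hotspot at the bump center
  rr <- matrix(0:31, 32, 32); cc <- t(rr)
  bump <- exp(-((rr - 12)^2 + (cc - 20)^2) / (2 * 2^2))
  sig <- 0.05 + bump
  amap <- ActivityMap(mu = matrix(1, 32, 32), sigma = sig)
  hs <- detectHotspots(amap, kSigma = 3, minArea = 4)
  expect_length(hs, 1L)
  argmax <- which(sig == max(sig), arr.ind = TRUE) - 1  # exhaustive oracle
  expect_lt(max(abs(hs[[1]]@centroid - argmax)), 0.5)

  ## two equal bumps: two hotspots, tie broken lexicographically
  sig2 <- 0.05 + exp(-((rr - 8)^2 + (cc - 8)^2) / 4) +
    exp(-((rr - 22)^2 + (cc - 24)^2) / 4)
  hs2 <- detectHotspots(ActivityMap(mu = matrix(1, 32, 32), sigma = sig2))
  expect_length(hs2, 2L)
  expect_equal(hs2[[1]]@peakSigma, hs2[[2]]@peakSigma, tolerance = 1e-9)
  expect_lt(hs2[[1]]@centroid[1], hs2[[2]]@centroid[1])

  ## empty mask is rejected
  expect_error(
    detectHotspots(ActivityMap(mu = matrix(1, 4, 4),
                               sigma = matrix(0, 4, 4),
                               mask = matrix(FALSE, 4, 4))),
    "empty")
})

test_that("detection recovers injected hotspots and stays silent on none", {
  bm <- BundleModel(waveform = "sinusoid", naturalFrequency = 12,
                    amplitude = 30)
  cam <- CameraModel()
  p <- StimulusProtocol("none", duration = 1.5)
  hits <- 0L; falsePositives <- 0L
  for (seed in 1:3) {
    sc <- demoScene(shape = c(48, 48), seed = seed)
    ds <- makeDataset(sc, bm, p, cam, "control", seed = seed)
    amap <- temporalStats(ds$stacks$z0, normalize = TRUE,
                          background = backgroundRoi(sc),
                          mask = somaMask(sc))
    hs <- detectHotspots(amap)
    tab <- hotspotTable(hs)
    truec <- sc@hotspots[[1]]@center
    if (nrow(tab) >= 1 &&
        min(sqrt((tab$row - truec[1])^2 + (tab$col - truec[2])^2)) < 2)
      hits <- hits + 1L

    scEmpty <- demoScene(shape = c(48, 48), hotspots = list(), seed = seed)
    dsE <- makeDataset(scEmpty, bm, p, cam, "control", seed = seed)
    amapE <- temporalStats(dsE$stacks$z0, normalize = TRUE,
                           background = backgroundRoi(scEmpty),
                           mask = somaMask(scEmpty))
    falsePositives <- falsePositives + length(detectHotspots(amapE))
  }
  expect_identical(hits, 3L)
  expect_identical(falsePositives, 0L)
})

test_that("delta-I over I extraction matches hand arithmetic", {
  ## toy: roi disk uniformly 110/120/130, background uniformly 100
  arr <- array(100, c(24, 24, 3))
  roi <- Roi(c(6, 6), 2)
  bg <- Roi(c(16, 16), 2, label = "background")
  rmask <- diskMask(c(24, 24), c(6, 6), 2)
  for (k in 1:3) {
    fr <- arr[, , k]
    fr[rmask] <- 100 + 10 * k
    arr[, , k] <- fr
  }
  st <- ImageStack(arr, frameRate = 1000)
  expect_equal(traceValues(extractTrace(st, roi, bg)), c(0.1, 0.2, 0.3),
               tolerance = 1e-12)

  ## self-normalization: roi identical to background level -> zeros
  st0 <- ImageStack(array(250L, c(24, 24, 3)), frameRate = 1000)
  expect_equal(traceValues(extractTrace(st0, roi, bg)), rep(0, 3))

  ## ratio case: roi = 2x background -> constant 1
  arr2 <- array(100, c(24, 24, 3)); arr2[rep(rmask, 3)] <- 200
  st2 <- ImageStack(arr2, frameRate = 1000)
  expect_equal(traceValues(extractTrace(st2, roi, bg)), rep(1, 3))

  ## overlapping disks are rejected
  expect_error(extractTrace(st, roi, Roi(c(7, 7), 2, label = "background")),
               "disjoint")
})

test_that("depth profiles reflect bundle-hotspot coupling", {
  fs <- 1000
  n <- 5000
  x <- sin(2 * pi * 9 * (0:(n - 1)) / fs)
  bundle <- Trace(x, fs)
  ## identical traces: perfect correlation at zero lag
  zp <- zProfile(list(z0 = Trace(x, fs, "delta_i_over_i")), bundle)
  expect_equal(zp$maxCorr, 1, tolerance = 1e-9)
  expect_identical(zp$lag, 0L)

  ## independent white noise: max correlation stays below threshold
  set.seed(33)
  worst <- 0
  for (rep in 1:100) {
    a <- Trace(rnorm(n), fs)
    b <- Trace(rnorm(n), fs)
    r <- maxShiftCorrelation(a, b)
    worst <- max(worst, abs(maxCorr(r)))
  }
  expect_lt(worst, 0.2)

  ## attenuation with depth: correlation non-increasing beyond injection
  set.seed(34)
  att <- c(1, 0.7, 0.5, 0.3, 0.2, 0.1)
  traces <- lapply(seq_along(att), function(i)
    list(zIndex = i - 1L,
         trace = Trace(att[i] * x + rnorm(n, sd = 0.7), fs,
                       "delta_i_over_i")))
  zp2 <- zProfile(traces, bundle)
  expect_true(all(diff(zp2$maxCorr) < 0.02))
})
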