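test_that("on-bin sinusoids give exact spectral amplitudes", {
  fs <- 1000
  t <- (0:4999) / fs
  sp <- normalizedSpectrum(Trace(sin(2 * pi * 10 * t), fs))
  i <- which.max(amplitudes(sp))
  expect_equal(frequencies(sp)[i], 10)
  expect_equal(amplitudes(sp)[i], 1, tolerance = 1e-10)

  ## max normalization peaks at exactly 1; a zero trace cannot be normalized
  spn <- normalizedSpectrum(Trace(3 * sin(2 * pi * 10 * t), fs),
                            normalization = "max")
  expect_identical(max(amplitudes(spn)), 1)
  expect_error(normalizedSpectrum(Trace(rep(0, 100), fs),
                                  normalization = "max"), "zero trace")
  expect_error(normalizedSpectrum(Trace(rnorm(8), fs)), "too short")
})

test_that("spectrum agrees with the direct-summation DFT oracle", {
  set.seed(12)
  for (m in c(64, 101)) {
    x <- rnorm(m)
    sp <- normalizedSpectrum(Trace(x, 500))
    expect_equal(amplitudes(sp), oracleDftAmplitudes(x), tolerance = 1e-8)
    expect_equal(frequencies(sp), (0:(floor(m / 2))) * 500 / m)
  }
})

test_that("on-bin spectral energy satisfies the Parseval identity", {
  ## for a mean-removed on-bin composition, sum(a^2) * M / 2 = sum(x^2)
  fs <- 1000; m <- 2000
  t <- (0:(m - 1)) / fs
  x <- 2.5 * sin(2 * pi * 10 * t) + 1.2 * cos(2 * pi * 40 * t) +
    0.4 * sin(2 * pi * 155 * t)
  sp <- normalizedSpectrum(Trace(x, fs))
  expect_equal(sum(amplitudes(sp)^2) * m / 2, sum((x - mean(x))^2),
               tolerance = 1e-8)
})

test_that("peak metrics honor bands and resolve ties downward", {
  fs <- 1000
  t <- (0:1999) / fs
  x <- 2 * sin(2 * pi * 50 * t) + 1 * sin(2 * pi * 120 * t)
  sp <- normalizedSpectrum(Trace(x, fs))
  expect_equal(peakMetrics(sp)$peakFrequency, 50)
  expect_equal(peakMetrics(sp, band = c(100, 400))$peakFrequency, 120)
  expect_equal(peakMetrics(sp, band = c(100, 400))$peakAmplitude, 1,
               tolerance = 1e-9)
  expect_error(peakMetrics(sp, band = c(501, 600)), "empty")

  ## random spectrum vs exhaustive scan
  set.seed(3)
  x2 <- rnorm(512)
  sp2 <- normalizedSpectrum(Trace(x2, fs))
  pm <- peakMetrics(sp2)
  a <- amplitudes(sp2); f <- frequencies(sp2)
  best <- which(a == max(a[-1]))
  expect_equal(pm$peakFrequency, f[min(best)])

  ## an exact tie resolves to the lower frequency
  spTie <- new("Spectrum", frequencies = c(0, 1, 2, 3),
               amplitudes = c(0, 0.5, 0.7, 0.7), normalization = "none",
               sampleRate = 8)
  expect_equal(peakMetrics(spTie, band = c(1, 3))$peakFrequency, 2)
})

test_that("peak amplitude change is plain percent arithmetic", {
  expect_equal(peakAmplitudeChange(2.0, 0.70), -65)
  expect_equal(peakAmplitudeChange(1.37, 1.37), 0)
  expect_equal(peakAmplitudeChange(1.0, 1.07), 7)
  expect_error(peakAmplitudeChange(0, 1), "positive")
  expect_error(peakAmplitudeChange(-2, 1), "positive")
})

test_that("maximal lagged correlation recovers known shifts", {
  fs <- 1000
  ## incommensurate components: no periodic aliases inside the lag range
  t <- (0:999) / fs
  x <- sin(2 * pi * 9.7 * t) + 0.2 * sin(2 * pi * 3.1 * t)
  a <- Trace(x, fs)
  ## self-correlation: exactly 1 at zero lag
  r0 <- maxShiftCorrelation(a, a, maxLag = 100)
  expect_equal(maxCorr(r0), 1, tolerance = 1e-12)
  expect_identical(corrLag(r0), 0L)

  ## a 20-sample (20 ms) delayed copy is found at lag exactly 20
  b <- Trace(c(rep(0, 20), x[1:980]), fs)
  r <- maxShiftCorrelation(a, b, maxLag = 100)
  expect_identical(corrLag(r), 20L)
  expect_gt(maxCorr(r), 0.999)
  expect_equal(r@lagSeconds, 0.020)
})

test_that("lag scan matches the brute-force oracle", {
  set.seed(19)
  for (rep in 1:5) {
    na <- sample(150:250, 1)
    a <- Trace(rnorm(na), 1000)
    b <- Trace(rnorm(sample(150:250, 1)), 1000)
    got <- maxShiftCorrelation(a, b, maxLag = 50)
    want <- oracleMaxShiftCorr(traceValues(a), traceValues(b), 50)
    expect_equal(maxCorr(got), want$maxCorr, tolerance = 1e-12)
    expect_identical(corrLag(got), as.integer(want$lag))
  }
})

test_that("lag scan is symmetric under swapping with lag negation", {
  set.seed(23)
  a <- Trace(rnorm(400), 1000)
  b <- Trace(rnorm(400), 1000)
  r1 <- maxShiftCorrelation(a, b, maxLag = 60)
  r2 <- maxShiftCorrelation(b, a, maxLag = 60)
  expect_equal(maxCorr(r1), maxCorr(r2), tolerance = 1e-12)
  expect_identical(corrLag(r1), -corrLag(r2))
})

test_that("degenerate correlation inputs are rejected", {
  fs <- 1000
  const <- Trace(rep(1, 100), fs)
  noise <- Trace(rnorm(100), fs)
  expect_error(maxShiftCorrelation(const, noise, maxLag = 10),
               "variance|overlap")
  expect_error(maxShiftCorrelation(Trace(rnorm(10), fs),
                                   Trace(rnorm(10), fs)), "32 samples")
  expect_error(maxShiftCorrelation(noise, Trace(rnorm(100), 500)),
               "sample rate")
})

test_that("null maximal correlations stay below the 0.2 threshold", {
  ## Monte-Carlo null for independent stationary noise: the conservative
  ## classification threshold of 0.2 sits far above the null tail
  set.seed(77)
  n <- 2000
  vals <- replicate(200, {
    r <- maxShiftCorrelation(Trace(rnorm(n), 1000), Trace(rnorm(n), 1000),
                             maxLag = 200)
    maxCorr(r)
  })
  expect_lt(stats::quantile(vals, 0.99), 0.2)
  expect_lt(max(vals), 0.25)
})

test_that("threshold classification is inclusive at the boundary", {
  mk <- function(r) new("CorrelationResult", maxCorr = r, lag = 0L,
                        threshold = 0.2, correlated = r >= 0.2,
                        lagSeconds = 0)
  expect_true(classifyCorrelated(mk(0.25)))
  expect_false(classifyCorrelated(mk(0.19)))
  expect_true(classifyCorrelated(mk(0.2)))
  expect_true(isCorrelated(mk(0.2)))
})
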