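# Independent brute-force oracles the implementation must agree with.

# Per-pixel double-loop temporal statistics (population SD), with optional
# per-frame background normalization. Deliberately naive.
oracleTemporalStats <- function(arr, normalize = FALSE, bgMask = NULL) {
  d <- dim(arr)
  mu <- matrix(0, d[1L], d[2L])
  sig <- matrix(0, d[1L], d[2L])
  a <- arr
  storage.mode(a) <- "double"
  if (normalize) {
    for (k in seq_len(d[3L])) {
      fr <- a[, , k]
      f <- if (is.null(bgMask)) mean(fr) else mean(fr[bgMask])
      a[, , k] <- fr / f
    }
  }
  for (r in seq_len(d[1L])) {
    for (cc in seq_len(d[2L])) {
      v <- a[r, cc, ]
      m <- sum(v) / d[3L]
      mu[r, cc] <- m
      sig[r, cc] <- sqrt(sum((v - m)^2) / d[3L])
    }
  }
  list(mu = mu, sigma = sig)
}

# Per-lag Pearson correlation by direct cor() calls, with the same
# tie-break rules (smallest |lag|, then negative lag).
oracleMaxShiftCorr <- function(a, b, maxLag, minOverlapFrac = 0.5) {
  na <- length(a); nb <- length(b)
  best <- -Inf; bestLag <- NA_integer_
  for (h in (-maxLag):maxLag) {
    i0 <- max(1L, 1L - h); i1 <- min(na, nb - h)
    n <- i1 - i0 + 1L
    if (n < minOverlapFrac * min(na, nb) || n < 2L) next
    x <- a[i0:i1]; y <- b[(i0 + h):(i1 + h)]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y)
    better <- r > best ||
      (r == best && (abs(h) < abs(bestLag) ||
                     (abs(h) == abs(bestLag) && h < bestLag)))
    if (better) { best <- r; bestLag <- h }
  }
  list(maxCorr = best, lag = bestLag)
}

# O(M^2) direct-summation DFT amplitude spectrum with the package's
# amplitude convention (mean removed; 2|X|/M; DC and Nyquist factor 1).
oracleDftAmplitudes <- function(x) {
  m <- length(x)
  x <- x - mean(x)
  nh <- floor(m / 2) + 1L
  amp <- numeric(nh)
  t <- 0:(m - 1)
  for (j in 0:(nh - 1L)) {
    re <- sum(x * cos(2 * pi * j * t / m))
    im <- -sum(x * sin(2 * pi * j * t / m))
    amp[j + 1L] <- 2 * sqrt(re^2 + im^2) / m
  }
  amp[1L] <- amp[1L] / 2
  if (m %% 2L == 0L) amp[nh] <- amp[nh] / 2
  amp
}

# Least-squares quadrature estimator of a single-frequency amplitude:
# regression on sin/cos (plus intercept) over the segment.
oracleQuadratureAmp <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
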