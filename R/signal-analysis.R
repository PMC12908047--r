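#' @include AllClasses.R utils.R
NULL

#' One-sided amplitude spectrum of a trace
#'
#' The mean-subtracted trace is Fourier transformed without zero padding
#' (frequency resolution = sampleRate / M). Amplitudes are scaled as
#' \code{a(f) = 2 |X(f)| / M} so that a pure sinusoid of amplitude A at an
#' on-bin frequency yields \code{a(f0) = A}; the DC and (for even M)
#' Nyquist bins carry factor 1 instead of 2. With \code{window = "hann"}
#' the trace is tapered and the amplitude scale corrected by the window
#' sum, trading leakage for peak amplitude accuracy on off-bin tones.
#'
#' @param trace a \linkS4class{Trace} of length >= 16
#' @param window \code{"none"} or \code{"hann"}
#' @param normalization \code{"none"} (amplitudes in trace units) or
#'   \code{"max"} (divide by the peak; errors on an all-zero trace)
#' @return a \linkS4class{Spectrum}
#' @examples
#' tr <- Trace(sin(2 * pi * 10 * (0:4999) / 1000), 1000)
#' sp <- normalizedSpectrum(tr)
#' frequencies(sp)[which.max(amplitudes(sp))]   # 10 Hz
#' @export
normalizedSpectrum <- function(trace, window = c("none", "hann"),
                               normalization = c("none", "max")) {
  window <- match.arg(window)
  normalization <- match.arg(normalization)
  x <- trace@values
  m <- length(x)
  if (m < 16L) stop("trace too short for a spectrum (need >= 16 samples)")
  x <- x - mean(x)
  scale <- m
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1)))
    x <- x * w
    scale <- sum(w)
  }
  X <- stats::fft(x)
  nh <- floor(m / 2) + 1L
  amp <- 2 * Mod(X[seq_len(nh)]) / scale
  amp[1L] <- amp[1L] / 2
  if (m %% 2L == 0L) amp[nh] <- amp[nh] / 2
  freqs <- (0:(nh - 1L)) * trace@sampleRate / m
  if (normalization == "max") {
    pk <- max(amp)
    if (pk == 0) stop("cannot max-normalize the spectrum of a zero trace")
    amp <- amp / pk
    amp[which.max(amp)] <- 1   # guard rounding in the validity check
  }
  new("Spectrum", frequencies = freqs, amplitudes = amp,
      normalization = normalization, sampleRate = trace@sampleRate)
}

#' Peak frequency and amplitude of a spectrum within a band
#'
#' @param spec a \linkS4class{Spectrum}
#' @param band \code{c(f_lo, f_hi)} in Hz (inclusive); \code{NULL} uses the
#'   full positive-frequency range
#' @return named list \code{peakFrequency}, \code{peakAmplitude}; exact
#'   amplitude ties resolve to the lower frequency
#' @export
peakMetrics <- function(spec, band = NULL) {
  stopifnot(is(spec, "Spectrum"))
  f <- spec@frequencies
  a <- spec@amplitudes
  if (is.null(band)) band <- c(f[2L], f[length(f)])
  keep <- which(f >= band[1L] & f <= band[2L])
  if (!length(keep)) stop("empty frequency band")
  i <- keep[which.max(a[keep])]   # which.max: first index, i.e. lowest f
  list(peakFrequency = f[i], peakAmplitude = a[i])
}

#' Percent change of a spectral peak amplitude between conditions
#'
#' \code{100 * (treated - control) / control}: the summary used to compare
#' hotspot activity before and after a pharmacological treatment.
#'
#' @param controlAmp peak amplitude under control conditions (> 0)
#' @param treatedAmp peak amplitude after treatment
#' @return the percent change (negative = suppression)
#' @examples
#' peakAmplitudeChange(2.0, 0.70)   # -65
#' @export
peakAmplitudeChange <- function(controlAmp, treatedAmp) {
  if (!is.finite(controlAmp) || controlAmp <= 0)
    stop("controlAmp must be a positive number")
  100 * (treatedAmp - controlAmp) / controlAmp
}

## Pearson correlation of a and b at every lag in [-maxLag, maxLag], each
## over the overlapping segment only, re-centered and re-scaled there.
## Positive lag pairs a[t] with b[t + lag] (b delayed relative to a).
## Implemented with FFT cross-products + prefix sums; the testthat suite
## holds a brute-force per-lag oracle this must agree with to 1e-12.
.lagCorrelations <- function(a, b, maxLag) {
  na <- length(a); nb <- length(b)
  L <- stats::nextn(na + nb, 2)
  fa <- stats::fft(c(a, numeric(L - na)))
  fb <- stats::fft(c(b, numeric(L - nb)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / L
  ## cc[k] = sum_t a[t] * b[t + (k-1) mod L]: lag h >= 0 at index h + 1,
  ## lag h < 0 at index L + h + 1
  lags <- (-maxLag):maxLag
  sab <- numeric(length(lags))
  pos <- lags >= 0L
  sab[pos] <- cc[lags[pos] + 1L]
  sab[!pos] <- cc[L + lags[!pos] + 1L]
  csa <- cumsum(a); csa2 <- cumsum(a^2)
  csb <- cumsum(b); csb2 <- cumsum(b^2)
  rsum <- function(cs, i0, i1)          # sum over i0:i1 (1-based), i0 <= i1
    cs[i1] - if (i0 > 1L) cs[i0 - 1L] else 0
  n <- integer(length(lags))
  r <- rep(NA_real_, length(lags))
  for (j in seq_along(lags)) {
    h <- lags[j]
    i0 <- max(1L, 1L - h)               # a-index window
    i1 <- min(na, nb - h)
    if (i1 < i0 + 1L) { n[j] <- max(0L, i1 - i0 + 1L); next }
    nn <- i1 - i0 + 1L
    n[j] <- nn
    sa <- rsum(csa, i0, i1); sa2 <- rsum(csa2, i0, i1)
    sb <- rsum(csb, i0 + h, i1 + h); sb2 <- rsum(csb2, i0 + h, i1 + h)
    va <- sa2 - sa^2 / nn
    vb <- sb2 - sb^2 / nn
    scale2 <- va * vb
    if (scale2 <= .Machine$double.eps * nn * max(sa2, sb2, 1)) next
    r[j] <- (sab[j] - sa * sb / nn) / sqrt(scale2)
  }
  list(lags = lags, r = r, n = n)
}

#' Maximum lagged Pearson correlation between two traces
#'
#' Scans every integer lag in \code{[-maxLag, maxLag]}; at each lag the
#' Pearson coefficient is computed over the overlapping samples only (both
#' segments re-centered and re-scaled over the overlap). Positive lag means
#' the second trace is delayed relative to the first. Returns the maximum
#' signed coefficient (or of \code{|r|} with \code{absolute = TRUE}) and
#' its lag; exact ties resolve to the smallest \code{|lag|}, then to the
#' negative lag. Lags whose overlap falls below
#' \code{minOverlapFrac * min(length(a), length(b))} or whose overlap has
#' zero variance are skipped.
#'
#' @param a,b \linkS4class{Trace} objects with equal sample rates and
#'   lengths >= 32
#' @param maxLag maximum lag in samples; default
#'   \code{min(floor(min(Na, Nb) / 2), 500)}
#' @param minOverlapFrac minimum overlap fraction (default 0.5)
#' @param threshold classification threshold stored in the result
#'   (default 0.2)
#' @param absolute maximize \code{|r|} instead of the signed coefficient
#' @return a \linkS4class{CorrelationResult}
#' @examples
#' x <- sin(2 * pi * 10 * (0:999) / 1000)
#' a <- Trace(x, 1000)
#' b <- Trace(c(rep(0, 20), x[1:980]), 1000)   # delayed copy
#' r <- maxShiftCorrelation(a, b, maxLag = 100)
#' corrLag(r)   # 20
#' @export
maxShiftCorrelation <- function(a, b, maxLag = NULL, minOverlapFrac = 0.5,
                                threshold = 0.2, absolute = FALSE) {
  stopifnot(is(a, "Trace"), is(b, "Trace"))
  .assertSameRate(a, b)
  na <- length(a@values); nb <- length(b@values)
  if (na < 32L || nb < 32L)
    stop("traces must hold at least 32 samples")
  if (is.null(maxLag)) maxLag <- min(floor(min(na, nb) / 2), 500L)
  maxLag <- as.integer(maxLag)
  res <- .lagCorrelations(a@values, b@values, maxLag)
  minN <- minOverlapFrac * min(na, nb)
  ok <- !is.na(res$r) & res$n >= minN
  if (!any(ok))
    stop("no lag with sufficient overlap and non-degenerate variance")
  score <- if (absolute) abs(res$r) else res$r
  best <- max(score[ok])
  cand <- which(ok & score == best)
  cand <- cand[order(abs(res$lags[cand]), res$lags[cand])]
  j <- cand[1L]
  lag <- res$lags[j]
  new("CorrelationResult", maxCorr = res$r[j], lag = as.integer(lag),
      threshold = threshold, correlated = res$r[j] >= threshold,
      lagSeconds = lag / a@sampleRate)
}

#' Classify a correlation result against a threshold
#'
#' The boundary is inclusive: a maximal correlation exactly at the
#' threshold counts as correlated. The default 0.2 is a conservative limit
#' roughly 4 SDs above the null distribution of maximal lagged correlations
#' between independent bundle recordings.
#'
#' @param result a \linkS4class{CorrelationResult}
#' @param threshold classification threshold (default 0.2)
#' @return \code{TRUE} iff \code{maxCorr(result) >= threshold}
#' @examples
#' classifyCorrelated(
#'   new("CorrelationResult", maxCorr = 0.25, lag = 0L, threshold = 0.2,
#'       correlated = TRUE, lagSeconds = 0))
#' @export
classifyCorrelated <- function(result, threshold = 0.2) {
  stopifnot(is(result, "CorrelationResult"))
  result@maxCorr >= threshold
}
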