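#' @include AllClasses.R utils.R
NULL

## 1D Gaussian-plus-offset fit to axis-projected (proj, intensity) samples;
## returns the center or NA on non-convergence. The offset term absorbs the
## residual background so the center estimate is not pulled toward the ROI
## center the way a plain centroid is.
.fitGaussCenter <- function(proj, w, startCenter, startSigma) {
  df <- data.frame(p = proj, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      w ~ a * exp(-(p - m)^2 / (2 * s^2)) + b,
      data = df,
      start = list(a = max(w), m = startCenter, s = startSigma, b = 0),
      lower = c(a = 0, m = min(proj), s = 0.3, b = -Inf),
      upper = c(a = Inf, m = max(proj), s = diff(range(proj)), b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  stats::coef(fit)[["m"]]
}

#' Track hair-bundle displacement at sub-pixel resolution
#'
#' Per frame, the intensity profile inside the bundle ROI is projected onto
#' the motion axis after subtracting a per-frame floor (the 10th intensity
#' percentile of the ROI, which makes the tracker invariant to uniform
#' offsets and robust to shot noise). The \code{"centroid"} method returns
#' the intensity-weighted mean projected position; \code{"gaussian_fit"}
#' refines it with a least-squares 1D Gaussian whose center is used instead
#' (falling back to the centroid, with a warning, on non-convergence).
#' Displacement is \code{(position - baseline) * pixelPitch} in nm.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param cfg a \linkS4class{TrackerConfig}
#' @return a \linkS4class{Trace} of kind \code{"displacement_nm"}
#' @examples
#' sc <- demoScene(shape = c(32, 32), hotspots = list())
#' bm <- BundleModel(waveform = "sinusoid", amplitude = 0,
#'                   positionNoiseSd = 0)
#' tr <- simulateBundle(bm, StimulusProtocol("none", duration = 0.05))
#' st <- renderStack(sc, makeGroundTruth(sc, tr), CameraModel(),
#'                   noise = FALSE)
#' cfg <- TrackerConfig(Roi(c(7, 16), 6, label = "bundle"))
#' max(abs(traceValues(trackBundle(st, cfg))))   # static bundle: 0
#' @export
trackBundle <- function(stack, cfg) {
  stopifnot(is(stack, "ImageStack"), is(cfg, "TrackerConfig"))
  d <- dim(stack@frames)
  m <- .roiMask(d[1:2], cfg@roi)
  idx <- which(m)
  r0 <- (idx - 1L) %% d[1L]
  c0 <- (idx - 1L) %/% d[1L]
  proj <- r0 * cfg@axis[1L] + c0 * cfg@axis[2L]
  f <- stack@frames
  dim(f) <- c(d[1L] * d[2L], d[3L])
  sub <- f[idx, , drop = FALSE]
  storage.mode(sub) <- "double"
  n <- d[3L]
  pos <- numeric(n)
  fellBack <- 0L
  for (k in seq_len(n)) {
    v <- sub[, k]
    w <- pmax(v - stats::quantile(v, 0.1, names = FALSE), 0)
    tot <- sum(w)
    if (tot <= 0 || max(w) <= 0)
      stop("flat intensity profile in bundle ROI at frame ", k,
           ": no ridge to track")
    cen <- sum(w * proj) / tot
    if (cfg@method == "gaussian_fit") {
      g <- .fitGaussCenter(proj, w, cen, max(1, cfg@roi@radius / 3))
      if (is.na(g)) fellBack <- fellBack + 1L else cen <- g
    }
    pos[k] <- cen
  }
  if (fellBack > 0L)
    warning(sprintf(
      "gaussian fit did not converge in %d frame(s); centroid used", fellBack))
  base <- switch(cfg@baseline, mean = mean(pos), first_frame = pos[1L])
  Trace((pos - base) * stack@pixelPitch, sampleRate = stack@frameRate,
        kind = "displacement_nm")
}

#' Remove the mean or a linear trend from a trace
#'
#' @param trace a \linkS4class{Trace}
#' @param mode \code{"mean"} subtracts the mean; \code{"linear"} subtracts
#'   the least-squares line (drift removal before spectral analysis)
#' @return a \linkS4class{Trace} of the same length and kind
#' @examples
#' tr <- Trace(5 + (1:100) * 0.3, 1000)
#' max(abs(traceValues(detrendTrace(tr, "linear"))))   # ~0
#' @export
detrendTrace <- function(trace, mode = c("mean", "linear")) {
  mode <- match.arg(mode)
  x <- trace@values
  y <- switch(mode,
    mean = x - mean(x),
    linear = stats::lm.fit(cbind(1, seq_along(x)), x)$residuals)
  Trace(as.numeric(y), sampleRate = trace@sampleRate, kind = trace@kind,
        t0 = trace@t0)
}
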