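#' @include AllClasses.R utils.R
NULL

#' Construct an ActivityMap
#'
#' Usually produced by \code{\link{temporalStats}}; the constructor is
#' exported for tests and for importing externally computed maps.
#'
#' @param mu temporal mean matrix
#' @param sigma temporal SD matrix
#' @param mask logical analysis-region matrix (default: all pixels)
#' @param normalized whether frames were background-normalized first
#' @return an \linkS4class{ActivityMap}
#' @export
ActivityMap <- function(mu, sigma, mask = NULL, normalized = FALSE) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(mu), ncol(mu))
  new("ActivityMap", mu = mu, sigma = sigma, mask = mask,
      normalized = normalized)
}

#' Per-pixel temporal mean and standard deviation of a recording
#'
#' Computes the activity heatmap: for each pixel, the temporal mean
#' \code{mu = (1/N) sum_k I_k} and the population-normalized temporal SD
#' \code{sigma = sqrt((1/N) sum_k (I_k - mu)^2)} over the N frames. With
#' \code{normalize = TRUE} each frame is first divided by its spatial mean
#' over the background region (the whole frame when no background is
#' given), which cancels frame-wide illumination drifts.
#'
#' @param stack an \linkS4class{ImageStack} (N >= 2 frames)
#' @param normalize divide each frame by its spatial background mean first
#' @param background a \linkS4class{Roi} or logical matrix marking the
#'   background region used for normalization; \code{NULL} = whole frame
#' @param mask optional logical analysis-region matrix stored in the result
#'   (used by \code{\link{detectHotspots}}); default: all pixels
#' @return an \linkS4class{ActivityMap}
#' @examples
#' st <- ImageStack(array(rep(c(100L, 200L), each = 16), c(4, 4, 2)),
#'                  frameRate = 1000)
#' amap <- temporalStats(st, normalize = FALSE)
#' muMap(amap)[1, 1]      # 150
#' sigmaMap(amap)[1, 1]   # 50
#' @export
temporalStats <- function(stack, normalize = TRUE, background = NULL,
                          mask = NULL) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@frames)
  n <- d[3L]
  if (n < 2L) stop("temporal statistics need at least 2 frames")
  npix <- d[1L] * d[2L]
  f <- stack@frames
  dim(f) <- c(npix, n)
  storage.mode(f) <- "double"
  if (normalize) {
    bgIdx <- if (is.null(background)) {
      seq_len(npix)
    } else if (is(background, "Roi")) {
      which(.roiMask(d[1:2], background))
    } else {
      which(background)
    }
    factors <- colMeans(f[bgIdx, , drop = FALSE])
    if (any(factors == 0))
      stop("background region has zero mean in at least one frame")
    f <- sweep(f, 2L, factors, "/")
  }
  mu <- rowMeans(f)
  sig <- sqrt(rowMeans((f - mu)^2))
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  ActivityMap(mu = matrix(mu, d[1L], d[2L]),
              sigma = matrix(sig, d[1L], d[2L]),
              mask = mask, normalized = normalize)
}

#' Detect activity hotspots on a sigma map
#'
#' Pixels with \code{sigma > mean(sigma | mask) + kSigma * sd(sigma | mask)}
#' are grouped by 8-connectivity; components of at least \code{minArea}
#' pixels become hotspots, each assigned a circular ROI of radius
#' \code{roiRadius} centered at the sigma-weighted component centroid.
#' Hotspots are returned sorted by peak sigma, descending; exact ties are
#' broken by (row, col) lexicographic order of the centroids.
#'
#' @param amap an \linkS4class{ActivityMap}
#' @param kSigma detection threshold in robustness units (default 3)
#' @param minArea minimum component area in px (default 4)
#' @param roiRadius ROI radius assigned to each hotspot (default 5 px,
#'   about 0.54 um at 108.3 nm/px)
#' @param zIndex z index recorded in the hotspot ROIs
#' @return list of \linkS4class{Hotspot} (possibly empty);
#'   see \code{\link{hotspotTable}} for a tabular view
#' @export
detectHotspots <- function(amap, kSigma = 3, minArea = 4, roiRadius = 5,
                           zIndex = NA_integer_) {
  stopifnot(is(amap, "ActivityMap"))
  if (!any(amap@mask)) stop("empty analysis mask")
  sig <- amap@sigma
  vals <- sig[amap@mask]
  thr <- mean(vals) + kSigma * stats::sd(vals)
  bw <- sig > thr & amap@mask
  lab <- .label8(bw)
  ncomp <- max(lab)
  if (ncomp == 0L) return(list())
  out <- list()
  for (comp in seq_len(ncomp)) {
    idx <- which(lab == comp)
    if (length(idx) < minArea) next
    w <- sig[idx]
    r0 <- (idx - 1L) %% nrow(sig)        # 0-based rows
    c0 <- (idx - 1L) %/% nrow(sig)       # 0-based cols
    centroid <- c(sum(r0 * w), sum(c0 * w)) / sum(w)
    out[[length(out) + 1L]] <- new("Hotspot",
      roi = Roi(centroid, radius = roiRadius, label = "hotspot",
                zIndex = as.integer(zIndex)),
      peakSigma = max(w), areaPx = length(idx), centroid = centroid)
  }
  if (!length(out)) return(list())
  peaks <- vapply(out, function(h) h@peakSigma, numeric(1L))
  rowc <- vapply(out, function(h) h@centroid[1L], numeric(1L))
  colc <- vapply(out, function(h) h@centroid[2L], numeric(1L))
  out[order(-peaks, rowc, colc)]
}

#' Extract a background-normalized intensity fluctuation trace
#'
#' Per frame k:
#' \code{dI/I[k] = (mean(I_k | roi) - mean(I_k | background)) /
#' mean(I_k | background)}, the standard normalization of fluorescence-style
#' trace extraction applied to label-free counts.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param roi the signal \linkS4class{Roi} (disk)
#' @param background the background \linkS4class{Roi}, disjoint from
#'   \code{roi} and outside the cell
#' @return a \linkS4class{Trace} of kind \code{"delta_i_over_i"} at the
#'   stack frame rate
#' @examples
#' st <- ImageStack(array(200L, c(16, 16, 3)), frameRate = 1000)
#' tr <- extractTrace(st, Roi(c(4, 4), 2), Roi(c(11, 11), 2, "background"))
#' traceValues(tr)   # all zero: ROI equals background
#' @export
extractTrace <- function(stack, roi, background) {
  stopifnot(is(stack, "ImageStack"), is(roi, "Roi"), is(background, "Roi"))
  d <- dim(stack@frames)
  mroi <- .roiMask(d[1:2], roi)
  mbg <- .roiMask(d[1:2], background)
  if (any(mroi & mbg)) stop("roi and background disks must be disjoint")
  f <- stack@frames
  dim(f) <- c(d[1L] * d[2L], d[3L])
  roiMean <- colMeans(f[which(mroi), , drop = FALSE])
  bgMean <- colMeans(f[which(mbg), , drop = FALSE])
  if (any(bgMean == 0)) stop("background mean is zero in at least one frame")
  Trace((roiMean - bgMean) / bgMean, sampleRate = stack@frameRate,
        kind = "delta_i_over_i")
}

#' Depth profile of bundle-hotspot coupling
#'
#' For a set of traces recorded at successive axial sections, computes the
#' maximal lagged Pearson correlation of each with the bundle trace.
#'
#' @param hotspotTraces a list of \code{list(zIndex =, trace =)} pairs, or a
#'   named list of \linkS4class{Trace} objects with names parseable as z
#'   indices (e.g. \code{"z0"})
#' @param bundle the bundle displacement \linkS4class{Trace}
#' @param maxLag,minOverlapFrac,threshold passed to
#'   \code{\link{maxShiftCorrelation}}
#' @return data.frame with columns \code{zIndex}, \code{maxCorr},
#'   \code{lag} (samples)
#' @export
zProfile <- function(hotspotTraces, bundle, maxLag = NULL,
                     minOverlapFrac = 0.5, threshold = 0.2) {
  entries <- lapply(seq_along(hotspotTraces), function(i) {
    el <- hotspotTraces[[i]]
    if (is(el, "Trace")) {
      nm <- names(hotspotTraces)[i]
      z <- if (!is.null(nm)) as.integer(sub("^z", "", nm)) else i - 1L
      list(zIndex = z, trace = el)
    } else el
  })
  rows <- lapply(entries, function(e) {
    .assertSameRate(e$trace, bundle)
    r <- maxShiftCorrelation(bundle, e$trace, maxLag = maxLag,
                             minOverlapFrac = minOverlapFrac,
                             threshold = threshold)
    data.frame(zIndex = e$zIndex, maxCorr = r@maxCorr, lag = r@lag)
  })
  do.call(rbind, rows)
}
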