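#' @include AllClasses.R
NULL

## Pixel coordinates are 0-based (row, col) throughout the public interface;
## internal matrix indexing converts with +1.

#' Logical disk mask for a circular ROI
#'
#' @param shape \code{(rows, cols)} of the target image
#' @param center \code{(row, col)} disk center, 0-based, sub-pixel allowed
#' @param radius disk radius in px; a pixel belongs to the disk when its
#'   center lies within \code{radius} of \code{center}
#' @return logical matrix of dim \code{shape}
#' @examples
#' sum(diskMask(c(21, 21), c(10, 10), 5))
#' @export
diskMask <- function(shape, center, radius) {
  r <- matrix(0:(shape[1L] - 1L), shape[1L], shape[2L])
  cc <- matrix(0:(shape[2L] - 1L), shape[1L], shape[2L], byrow = TRUE)
  (r - center[1L])^2 + (cc - center[2L])^2 <= radius^2
}

.roiMask <- function(shape, roi) {
  m <- diskMask(shape, roi@center, roi@radius)
  if (!any(m)) stop("ROI disk covers no pixels")
  if (roi@center[1L] - roi@radius < -0.5 ||
      roi@center[2L] - roi@radius < -0.5 ||
      roi@center[1L] + roi@radius > shape[1L] - 0.5 ||
      roi@center[2L] + roi@radius > shape[2L] - 0.5)
    stop("ROI disk extends beyond the image bounds")
  m
}

## 8-connected component labeling of a logical matrix (iterative BFS;
## written in-package because the available labeling routines are
## 4-connected only).
.label8 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  idx <- which(bw)
  if (!length(idx)) return(lab)
  cur <- 0L
  queue <- integer(length(idx))
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    queue[1L] <- s; qn <- 1L
    while (qn > 0L) {
      p <- queue[qn]; qn <- qn - 1L
      pr <- ((p - 1L) %% nr) + 1L
      for (k in seq_along(off)) {
        ## guard row wrap-around for the +-1 row moves
        dr <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)[k]
        if ((pr == 1L && dr == -1L) || (pr == nr && dr == 1L)) next
        q <- p + off[k]
        if (q < 1L || q > nr * nc) next
        if (bw[q] && lab[q] == 0L) {
          lab[q] <- cur
          qn <- qn + 1L
          if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qn] <- q
        }
      }
    }
  }
  lab
}

## Even-odd point-in-polygon test, vectorized over points.
## poly: n x 2 matrix (row, col), implicitly closed.
.pointsInPolygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1L]; xi <- poly[i, 2L]
    yj <- poly[j, 1L]; xj <- poly[j, 2L]
    crosses <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon into a logical mask
#'
#' @param shape \code{(rows, cols)}
#' @param poly n x 2 matrix of 0-based \code{(row, col)} vertices
#' @return logical matrix, TRUE for pixels whose center falls inside
#' @keywords internal
.polygonMask <- function(shape, poly) {
  r <- rep(0:(shape[1L] - 1L), times = shape[2L])
  cc <- rep(0:(shape[2L] - 1L), each = shape[1L])
  matrix(.pointsInPolygon(r, cc, poly), shape[1L], shape[2L])
}

## Gaussian FIR smoothing with edge replication; sigma in samples.
.gaussSmooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2L))[(half + 1L):(half + length(x))]
}

## Delay a sampled signal by d samples (d >= 0), padding with the first
## value; negative d advances, padding with the last value.
.delaySamples <- function(x, d) {
  n <- length(x)
  if (d == 0L) return(x)
  if (d > 0L) c(rep(x[1L], min(d, n)), x)[seq_len(n)]
  else c(x[(-d + 1L):n], rep(x[n], min(-d, n)))[seq_len(n)]
}

## Derived RNG streams: fixed offsets from one master seed, kept in integer
## range so conditions sharing a master seed share component noise.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1021 + offset) %% .Machine$integer.max)
}

.assertSameRate <- function(a, b) {
  if (abs(a@sampleRate - b@sampleRate) >
      1e-9 * max(a@sampleRate, b@sampleRate))
    stop("traces must share the same sample rate")
}
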