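#' @include AllClasses.R utils.R
NULL

## Metadata handling: the reader understands ImageJ-style description tags
## ("finterval=<s>" or "fps=<Hz>", "pixelpitch=<nm>") carried by third-party
## multi-page TIFFs; the writer persists metadata in a JSON sidecar
## (<path>.meta.json) because the TIFF writer in use cannot embed custom
## description tags. Explicit arguments always win over neither source.

.sidecarPath <- function(path) paste0(path, ".meta.json")

.parseImageJDescription <- function(desc) {
  out <- list()
  if (is.null(desc) || !nzchar(desc)) return(out)
  for (line in strsplit(desc, "\n", fixed = TRUE)[[1L]]) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) next
    key <- tolower(trimws(kv[1L]))
    val <- suppressWarnings(as.numeric(trimws(kv[2L])))
    if (is.na(val)) next
    if (key == "finterval" && val > 0) out$frameRate <- 1 / val
    if (key == "fps") out$frameRate <- val
    if (key %in% c("pixelpitch", "pixel_pitch")) out$pixelPitch <- val
    if (key %in% c("zindex", "z_index")) out$zIndex <- as.integer(val)
  }
  out
}

#' Read a multi-frame grayscale TIFF into an ImageStack
#'
#' Frames are kept in file order (TIFF page 0 becomes frame 1). Acquisition
#' metadata is taken, in order of precedence, from explicit arguments, from
#' an ImageJ-style description tag (\code{finterval}/\code{fps},
#' \code{pixelpitch}), or from the JSON sidecar written by
#' \code{\link{writeStack}}. Reading fails if no source supplies the frame
#' rate.
#'
#' @param path a readable multi-frame grayscale TIFF
#' @param frameRate acquisition rate (Hz); overrides file metadata
#' @param pixelPitch pixel size (nm/px); overrides file metadata
#' @param zIndex axial section index; overrides file metadata
#' @return an \linkS4class{ImageStack} of raw integer counts
#' @examples
#' st <- ImageStack(array(100L, c(4, 4, 3)), frameRate = 1000)
#' f <- tempfile(fileext = ".tif")
#' writeStack(st, f)
#' st2 <- readStack(f)
#' identical(frames(st2), frames(st))
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, frameRate = NULL, pixelPitch = NULL,
                      zIndex = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("an image stack needs at least 2 frames")
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop("not a grayscale stack: page has photometric interpretation '",
           attr(p, "color.space") %||% "RGB/multi-channel", "'")
  }
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1L))))
    stop("mixed page shapes in TIFF stack")
  bits <- attr(pages[[1L]], "bits.per.sample") %||% 16L
  meta <- .parseImageJDescription(attr(pages[[1L]], "description"))
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (k in c("frameRate", "pixelPitch", "zIndex"))
      if (is.null(meta[[k]]) && !is.null(sc[[k]])) meta[[k]] <- sc[[k]]
  }
  frameRate <- frameRate %||% meta$frameRate
  if (is.null(frameRate))
    stop("frame rate not found in TIFF metadata or sidecar; ",
         "supply frameRate=")
  pixelPitch <- pixelPitch %||% meta$pixelPitch %||% 108.3
  zIndex <- zIndex %||% meta$zIndex %||% NA_integer_
  arr <- array(0L, c(shp, length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  ImageStack(arr, frameRate = frameRate, pixelPitch = pixelPitch,
             zIndex = as.integer(zIndex), bitDepth = as.integer(bits),
             source = path)
}

#' Write an ImageStack as a lossless multi-frame grayscale TIFF
#'
#' Counts are written at the stack's bit depth without compression loss
#' (LZW is lossless); frame rate, pixel pitch and z index are persisted in a
#' JSON sidecar next to the file so that \code{\link{readStack}} round-trips
#' the metadata.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param path output file path
#' @return \code{path}, invisibly
#' @seealso \code{\link{readStack}}
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  maxval <- 2^stack@bitDepth - 1
  pages <- lapply(seq_len(nFrames(stack)),
                  function(k) stack@frames[, , k] / maxval)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = stack@bitDepth,
                    compression = "LZW", reduce = FALSE),
    error = function(e) stop("cannot write TIFF to ", path, ": ",
                             conditionMessage(e)))
  meta <- list(frameRate = stack@frameRate, pixelPitch = stack@pixelPitch,
               bitDepth = stack@bitDepth)
  if (!is.na(stack@zIndex)) meta$zIndex <- stack@zIndex
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace CSV
#'
#' Format: an initial comment line
#' \code{# kind=<kind> sample_rate=<Hz> t0=<s>} followed by a
#' \code{time_s,value} header and rows. The time column must be uniform to
#' within 1e-6 of the sample interval.
#'
#' @param path CSV file written by \code{\link{writeTrace}} (or compatible)
#' @return a \linkS4class{Trace}
#' @examples
#' tr <- Trace(c(0.1, 0.2, 0.3), 1000, "delta_i_over_i")
#' f <- tempfile(fileext = ".csv")
#' writeTrace(tr, f)
#' all.equal(traceValues(readTrace(f)), traceValues(tr))
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("cannot read trace CSV: ", path)
  first <- readLines(path, n = 1L)
  kind <- "displacement_nm"; rate <- NULL; t0 <- 0
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    for (tok in strsplit(sub("^#\\s*", "", first), "\\s+")[[1L]]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) next
      if (kv[1L] == "kind") kind <- kv[2L]
      if (kv[1L] == "sample_rate") rate <- as.numeric(kv[2L])
      if (kv[1L] == "t0") t0 <- as.numeric(kv[2L])
    }
  }
  df <- tryCatch(
    utils::read.csv(path, skip = skip, header = TRUE),
    error = function(e) stop("malformed trace CSV: ", conditionMessage(e)))
  if (!all(c("time_s", "value") %in% names(df)) || nrow(df) < 2L)
    stop("malformed trace CSV: need columns time_s,value and >= 2 rows")
  if (!is.numeric(df$time_s) || !is.numeric(df$value) ||
      anyNA(df$time_s) || anyNA(df$value))
    stop("malformed trace CSV: non-numeric entries")
  dt <- diff(df$time_s)
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > 1e-6 * step))
    stop("non-uniform time column (tolerance 1e-6 of the sample interval)")
  if (is.null(rate)) rate <- 1 / step
  Trace(df$value, sampleRate = rate, kind = kind, t0 = t0)
}

#' Write a trace CSV
#'
#' Values and times are written with 15 significant digits, so a
#' read/write round trip preserves the trace to better than 12 significant
#' digits.
#'
#' @param trace a \linkS4class{Trace}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s sample_rate=%s t0=%s", trace@kind,
                     format(trace@sampleRate, digits = 15),
                     format(trace@t0, digits = 15)), con)
  writeLines("time_s,value", con)
  tt <- trace@t0 + (seq_along(trace@values) - 1) / trace@sampleRate
  writeLines(paste(format(tt, digits = 15, trim = TRUE, scientific = FALSE),
                   format(trace@values, digits = 15, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
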