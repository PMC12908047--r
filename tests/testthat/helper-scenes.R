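# Shared synthetic-scene builders for the suite.

# A soma-plus-bundle scene with two healthy hotspots on the soma periphery,
# both modulated with the same lag.
twoHotspotScene <- function(shape = c(128, 128), lag = 0.020, gain = 0.002,
                            seed = 1L) {
  ctr <- c(0.62 * shape[1L], 0.5 * shape[2L])
  rad <- 0.28 * min(shape)
  demoScene(shape = shape, seed = seed, hotspots = list(
    HotspotSpec(center = round(c(ctr[1L], ctr[2L] - 0.75 * rad)),
                radiusPx = 5, zIndex = 0L, gain = gain, lag = lag),
    HotspotSpec(center = round(c(ctr[1L], ctr[2L] + 0.75 * rad)),
                radiusPx = 5, zIndex = 0L, gain = gain, lag = lag)))
}

# Tracker configuration matching demoScene()'s bundle ROI geometry.
demoTrackerConfig <- function(scene, method = "centroid") {
  rect <- scene@bundleRoi
  ctr <- c(mean(rect[1:2]), mean(rect[3:4]))
  rad <- min((rect[2L] - rect[1L]) / 2 + 3,
             ctr[1L] + 0.4, scene@imageShape[1L] - 1 - ctr[1L] - 0.1)
  TrackerConfig(Roi(ctr, rad, label = "bundle"), axis = scene@bundleAxis,
                method = method)
}

# A scene with a vertically centered bundle ridge and no soma/hotspots,
# for tracker accuracy tests: a wide disk ROI can then cover the full
# ridge over +-2 px shifts without asymmetric truncation.
ridgeScene <- function(shape = c(48, 48)) {
  SceneSpec(imageShape = shape,
            somaOutline = cbind(c(1, 4, 1), c(1, 1, 4)),  # inert corner
            bundleRoi = c(11, 37, 6, shape[2L] - 7),
            bundleAxis = c(0, 1), hotspots = list())
}

# Disk fully inside the ridge band: every ROI pixel obeys the
# ridge-plus-background model, so the Gaussian fit is exact.
ridgeTrackerConfig <- function(scene, method = "centroid") {
  TrackerConfig(Roi(c(24, (scene@imageShape[2L] - 1) / 2), 13,
                    label = "bundle"),
                axis = scene@bundleAxis, method = method)
}

# A minimal stack with a compact (finite-support) ridge whose translation
# between frames is an exact integer number of pixels. The ridge occupies
# rows fully covered by the tracker disk at every relevant column, so a
# shift permutes the floor-subtracted weights exactly and an unbiased
# tracker must recover it exactly. Pair with integerShiftRoi().
integerShiftStack <- function(shifts, shape = c(15, 41), pitch = 108.3) {
  profile <- c(1, 4, 9, 4, 1) * 50   # symmetric, compact support
  base <- 100
  arr <- array(base, c(shape, length(shifts)))
  c0 <- ceiling(shape[2L] / 2)       # 1-based center column
  rows <- 6:10                       # well inside the radius-6 disk
  for (k in seq_along(shifts)) {
    for (j in seq_along(profile)) {
      col <- c0 + shifts[k] + j - 3L
      arr[rows, col, k] <- base + profile[j]
    }
  }
  storage.mode(arr) <- "integer"
  ImageStack(arr, frameRate = 1000, pixelPitch = pitch)
}

integerShiftRoi <- function(stack) {
  d <- dim(frames(stack))
  Roi(c(7, (d[2L] - 1) / 2), 6, label = "bundle")
}
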