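# Shared fixtures: the clinical 62-frame schedule and lazily-built, cached
# phantom realizations (phantom construction is the expensive step).

.fixtures <- new.env(parent = emptyenv())

clinicalSchedule <- function() {
  if (is.null(.fixtures$sched))
    .fixtures$sched <- buildFrameSchedule(list(
      c(2, 10), c(30, 2), c(4, 10), c(8, 30), c(4, 60), c(5, 120),
      c(9, 300)))
  .fixtures$sched
}

# default study conditions, fixed seed
defaultPhantom <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- buildPhantom(phantomSpec(seed = 101),
                                      clinicalSchedule())
  .fixtures$default
}

# no blur, no noise: voxel values equal region curves exactly
cleanPhantom <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- buildPhantom(
      phantomSpec(psfFwhm = 0, noiseScale = 0, seed = 1), clinicalSchedule())
  .fixtures$clean
}

trueAifFine <- function() {
  t <- seq(0, 3900, by = 0.5)
  new("InputFunction", times = t, values = bolusAif(t), label = "truth")
}

# linear interpolation of an InputFunction onto a grid (test-side analogue
# of the package's internal resampling)
.ifOnGridExported <- function(f, grid) {
  stats::approx(ifTimes(f), ifValues(f), xout = grid, rule = 2)$y
}

coordKey <- function(m) {
  if (is(m, "VoxelMask") || is(m, "TACMatrix")) m <- maskCoords(m)
  paste(m[, 1], m[, 2], m[, 3])
}

# uniform two-tissue image (no geometry, no blur) with the phantom noise
# model applied; used for parameter-recovery experiments
twoRegionImage <- function(nPerRegion = 49, noiseScale = 0.5, seed = 42) {
  sched <- clinicalSchedule()
  aif <- trueAifFine()
  gm <- model2tcmIrr(kineticParams(0.173, 0.137, 0.053, 0.05), aif, sched)
  wm <- model2tcmIrr(kineticParams(0.061, 0.094, 0.025, 0.03), aif, sched)
  side <- ceiling(sqrt(nPerRegion))
  d <- c(side, side, 2L)
  arr <- array(0, c(d, nFrames(sched)))
  arr[, , 1, ] <- rep(gm, each = side * side)
  arr[, , 2, ] <- rep(wm, each = side * side)
  if (noiseScale > 0) {
    set.seed(seed)
    noise <- array(stats::rnorm(length(arr), 0,
                                noiseScale * sqrt(pmax(arr, 0) /
                                                    rep(frameDuration(sched),
                                                        each = prod(d)))),
                   dim(arr))
    arr <- arr + noise
  }
  img <- new("DynamicImage", values = arr, voxelSize = rep(1.65, 3),
             schedule = sched, fwhm = 0)
  list(image = img, gmSlice = 1L, wmSlice = 2L)
}
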