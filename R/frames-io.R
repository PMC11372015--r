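## Data preparation: frame schedules, dynamic-image I/O, brain masking and
## construction of the voxel x frame TAC matrix.

#' Build a frame schedule from a compact (count, duration) specification
#'
#' Dynamic PET protocols are usually written as blocks of equal-duration
#' frames, e.g. `2 x 10 s, 30 x 2 s, ...`. This expands such a block list
#' into explicit per-frame start times and durations, starting at 0 s.
#'
#' @param spec list of `c(count, duration_seconds)` pairs (or a 2-column
#'   matrix, one block per row).
#' @return a [FrameSchedule-class].
#' @examples
#' # a 65-min acquisition in 62 frames
#' sched <- buildFrameSchedule(list(
#'   c(2, 10), c(30, 2), c(4, 10), c(8, 30), c(4, 60), c(5, 120), c(9, 300)))
#' nFrames(sched)
#' totalTime(sched) / 60
#' @export
buildFrameSchedule <- function(spec) {
  if (is.matrix(spec)) spec <- split(spec, row(spec))
  if (!is.list(spec) || length(spec) == 0L)
    stop("frame specification must be a non-empty list of (count, duration)")
  counts <- vapply(spec, function(b) b[1], numeric(1))
  durs <- vapply(spec, function(b) b[2], numeric(1))
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != round(counts)))
    stop("frame counts must be positive integers")
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("frame durations must be > 0")
  duration <- rep(durs, times = counts)
  start <- c(0, cumsum(duration)[-length(duration)])
  new("FrameSchedule", start = start, duration = duration)
}

#' Frame mid-times
#'
#' Places each frame's activity at the middle of its acquisition window,
#' the time grid on which TACs are interpolated, peaks are located and
#' models are fitted.
#'
#' @param sched a [FrameSchedule-class].
#' @return numeric vector of mid-frame times (s), strictly increasing.
#' @export
frameMidtimes <- function(sched) {
  stopifnot(is(sched, "FrameSchedule"))
  sched@start + sched@duration / 2
}

#' Read / write a frame schedule as two-column text
#'
#' Plain CSV with columns `start_s` and `duration_s`, one row per frame.
#'
#' @param path file path.
#' @return `readFrameSchedule` returns a [FrameSchedule-class];
#'   `writeFrameSchedule` returns `path` invisibly.
#' @export
readFrameSchedule <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("start_s", "duration_s") %in% names(d)))
    stop("frame file must have columns start_s, duration_s")
  new("FrameSchedule", start = as.numeric(d$start_s),
      duration = as.numeric(d$duration_s))
}

#' @rdname readFrameSchedule
#' @param sched a [FrameSchedule-class].
#' @export
writeFrameSchedule <- function(sched, path) {
  utils::write.csv(data.frame(start_s = sched@start,
                              duration_s = sched@duration),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a 4D dynamic image (NIfTI-1)
#'
#' The fourth dimension holds the time frames. Voxel size is taken from (or
#' written to) the NIfTI `pixdim`; the frame schedule travels separately (see
#' [readFrameSchedule()]) because NIfTI has no standard slot for irregular
#' frame durations.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param sched a [FrameSchedule-class] for the image's time axis.
#' @param fwhm effective image resolution in mm (metadata only).
#' @return `readDynamicImage` returns a [DynamicImage-class].
#' @export
readDynamicImage <- function(path, sched, fwhm = 0) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  vs <- RNifti::pixdim(img)[1:3]
  new("DynamicImage", values = arr, voxelSize = as.numeric(vs),
      schedule = sched, fwhm = fwhm)
}

#' @rdname readDynamicImage
#' @param image a [DynamicImage-class].
#' @export
writeDynamicImage <- function(image, path) {
  stopifnot(is(image, "DynamicImage"))
  img <- RNifti::asNifti(image@values)
  RNifti::pixdim(img) <- c(image@voxelSize,
                           mean(image@schedule@duration))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Brain mask from a dynamic image
#'
#' A voxel enters the mask when its time-averaged activity exceeds 1 (strict,
#' in image units) and its axial position lies within the top
#' `axialExtent` mm of the image's non-zero support, emulating the head
#' coverage of a brain acquisition. The axial crop is applied from the most
#' superior non-zero slice downward, and excludes any inferior blood-pool
#' structures (e.g. a descending-aorta field of view) from the brain cohort.
#'
#' @param image a [DynamicImage-class]; the third axis is assumed
#'   inferior-to-superior.
#' @param axialExtent axial coverage in mm (default 200, i.e. 20 cm of head).
#' @return a [VoxelMask-class] in canonical lexicographic order. An image
#'   entirely below threshold yields an empty mask with a warning.
#' @export
brainMask <- function(image, axialExtent = 200) {
  stopifnot(is(image, "DynamicImage"))
  d <- dim(image@values)
  nvox <- prod(d[1:3])
  avg <- rowMeans(matrix(image@values, nvox, d[4]))
  dim(avg) <- d[1:3]
  # most superior slice with any non-zero signal
  nz <- which(apply(avg != 0, 3, any))
  if (length(nz) == 0L) {
    warning("image is identically zero; empty brain mask")
    return(new("VoxelMask", coords = matrix(integer(0), 0, 3)))
  }
  zc <- (seq_len(d[3]) - 0.5) * image@voxelSize[3]
  zTop <- zc[max(nz)]
  zOk <- zc > zTop - axialExtent
  keep <- avg > 1
  keep[, , !zOk] <- FALSE
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("no voxel exceeds the activity threshold; empty brain mask")
    return(new("VoxelMask", coords = matrix(integer(0), 0, 3)))
  }
  coords <- arrayInd(idx, d[1:3]) - 1L
  .newMask(coords)
}

# canonical lexicographic row order (x, then y, then z), 0-based coords
.newMask <- function(coords) {
  coords <- matrix(as.integer(coords), ncol = 3)
  o <- order(coords[, 1], coords[, 2], coords[, 3])
  new("VoxelMask", coords = coords[o, , drop = FALSE])
}

#' Extract the voxel x frame TAC matrix
#'
#' Rearranges the masked voxels of a 4D image into a 2D matrix whose row i is
#' the complete time course of voxel i. Row order is canonical (lexicographic
#' by coordinate) regardless of the order of the supplied mask.
#'
#' @param image a [DynamicImage-class].
#' @param mask a non-empty [VoxelMask-class].
#' @return a [TACMatrix-class].
#' @export
extractTacMatrix <- function(image, mask) {
  stopifnot(is(image, "DynamicImage"), is(mask, "VoxelMask"))
  if (nrow(mask@coords) == 0L) stop("mask is empty")
  d <- dim(image@values)
  if (any(mask@coords < 0L) ||
      any(sweep(mask@coords, 2, d[1:3] - 1L) > 0L))
    stop("mask coordinates outside image bounds")
  mask <- .newMask(mask@coords)
  lin <- 1L + mask@coords[, 1] +
    d[1] * (mask@coords[, 2] + d[2] * mask@coords[, 3])
  vmat <- matrix(image@values, prod(d[1:3]), d[4])
  new("TACMatrix", activities = vmat[lin, , drop = FALSE],
      coords = mask@coords, schedule = image@schedule)
}

#' Scatter TAC rows back into a volume
#'
#' Inverse of [extractTacMatrix()]: writes each row back to its voxel
#' coordinate, zero elsewhere.
#'
#' @param tacs a [TACMatrix-class].
#' @param dim integer(3) spatial grid dimensions.
#' @return a 4D array.
#' @export
scatterTacMatrix <- function(tacs, dim) {
  stopifnot(is(tacs, "TACMatrix"), length(dim) == 3L)
  n <- ncol(tacs@activities)
  out <- array(0, c(dim, n))
  lin <- 1L + tacs@coords[, 1] +
    dim[1] * (tacs@coords[, 2] + dim[2] * tacs@coords[, 3])
  vmat <- matrix(out, prod(dim), n)
  vmat[lin, ] <- tacs@activities
  array(vmat, c(dim, n))
}
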