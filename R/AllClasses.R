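#' @import methods
NULL

## ---------------------------------------------------------------------------
## FrameSchedule
## ---------------------------------------------------------------------------

#' Dynamic acquisition frame schedule
#'
#' Holds the per-frame start times and durations (seconds) of a dynamic PET
#' acquisition. Frames must be contiguous and non-overlapping, so the schedule
#' is fully determined by the first start time (always 0) and the duration
#' sequence.
#'
#' @slot start numeric vector of frame start times (s).
#' @slot duration numeric vector of frame durations (s).
#'
#' @seealso [buildFrameSchedule()], [frameMidtimes()]
#' @export
setClass("FrameSchedule",
         representation(start = "numeric", duration = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@start; d <- object@duration
  if (length(s) == 0L) return("schedule must contain at least one frame")
  if (length(s) != length(d)) return("start and duration lengths differ")
  if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite frame times")
  if (any(d <= 0)) return("frame durations must be > 0")
  if (s[1] != 0) return("first frame must start at 0 s")
  if (length(s) > 1L) {
    if (any(diff(s) <= 0)) return("frame starts must be strictly increasing")
    gap <- s[-1] - (s[-length(s)] + d[-length(d)])
    if (any(abs(gap) > 1e-9))
      return("frames must be contiguous: start[i+1] = start[i] + duration[i]")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## DynamicImage
## ---------------------------------------------------------------------------

#' 4D dynamic PET image
#'
#' A decay-corrected dynamic PET volume: an X x Y x Z x n array of activity
#' concentrations (kBq/mL) together with its voxel size, frame schedule and
#' the effective image resolution (FWHM of the point spread function, mm).
#'
#' @slot values 4D numeric array, fourth dimension = frames.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot schedule a [FrameSchedule-class].
#' @slot fwhm effective isotropic image resolution (mm); 0 if unknown.
#'
#' @export
setClass("DynamicImage",
         representation(values = "array", voxelSize = "numeric",
                        schedule = "FrameSchedule", fwhm = "numeric"))

setValidity("DynamicImage", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4D array (X, Y, Z, frames)")
  if (any(d[1:3] < 1L)) return("spatial dimensions must be >= 1")
  if (d[4] != length(object@schedule@start))
    return("fourth dimension must equal the number of frames in the schedule")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths (mm)")
  if (any(!is.finite(object@values))) return("activity values must be finite")
  if (length(object@fwhm) != 1L || object@fwhm < 0)
    return("fwhm must be a single non-negative length (mm)")
  TRUE
})

## ---------------------------------------------------------------------------
## VoxelMask
## ---------------------------------------------------------------------------

#' Set of voxel coordinates
#'
#' 0-based 3D voxel indices in canonical (lexicographic) order. Used for brain
#' masks and for the ground-truth region masks of the phantom.
#'
#' @slot coords integer matrix with 3 columns (x, y, z), 0-based.
#'
#' @export
setClass("VoxelMask", representation(coords = "matrix"))

setValidity("VoxelMask", function(object) {
  m <- object@coords
  if (ncol(m) != 3L) return("coords must have 3 columns")
  if (nrow(m) > 0L) {
    if (any(m < 0L)) return("coordinates must be 0-based non-negative indices")
    if (anyDuplicated(split(m, row(m))) > 0L ||
        anyDuplicated(m) > 0L) return("duplicate voxel coordinates")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## TACMatrix
## ---------------------------------------------------------------------------

#' Voxel x frame time-activity-curve matrix
#'
#' The 2D rearrangement of a masked dynamic image: row i holds the complete
#' time course of voxel i, rows ordered lexicographically by voxel coordinate.
#'
#' @slot activities M x n numeric matrix (kBq/mL).
#' @slot coords integer M x 3 matrix of 0-based voxel indices, one per row.
#' @slot schedule the originating [FrameSchedule-class].
#'
#' @export
setClass("TACMatrix",
         representation(activities = "matrix", coords = "matrix",
                        schedule = "FrameSchedule"))

setValidity("TACMatrix", function(object) {
  if (nrow(object@activities) != nrow(object@coords))
    return("one coordinate row per activity row required")
  if (ncol(object@activities) != length(object@schedule@start))
    return("columns must equal the number of frames")
  TRUE
})

## ---------------------------------------------------------------------------
## InputFunction
## ---------------------------------------------------------------------------

.IF_LABELS <- c("artery", "vein", "auto", "reference_da", "truth")

#' Labelled input-function curve
#'
#' An activity curve on a time grid, labelled by its origin: an arterial or
#' venous cluster average, the hybrid automatic IDIF, the descending-aorta
#' reference VOI, or phantom ground truth.
#'
#' @slot times seconds, strictly increasing.
#' @slot values kBq/mL, same length as `times`.
#' @slot label one of `"artery"`, `"vein"`, `"auto"`, `"reference_da"`,
#'   `"truth"`.
#'
#' @export
setClass("InputFunction",
         representation(times = "numeric", values = "numeric",
                        label = "character"))

setValidity("InputFunction", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have the same length")
  if (length(object@times) < 2L) return("need at least two time points")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (any(!is.finite(object@values))) return("values must be finite")
  if (length(object@label) != 1L || !(object@label %in% .IF_LABELS))
    return(paste("label must be one of:", paste(.IF_LABELS, collapse = ", ")))
  TRUE
})

## ---------------------------------------------------------------------------
## KineticParams
## ---------------------------------------------------------------------------

#' Irreversible 2TCM kinetic parameters
#'
#' Rate constants of the irreversible two-tissue compartment model for one
#' voxel or region, with the derived net influx rate Ki = K1*k3/(k2+k3).
#' All parameters are bounded to `[0, 1]` (the fitting box).
#'
#' @slot K1 plasma-to-tissue transport, mL/cm^3/min.
#' @slot k2 tissue-to-plasma efflux, 1/min.
#' @slot k3 phosphorylation rate, 1/min.
#' @slot vb blood volume fraction (dimensionless).
#' @slot Ki net influx rate, mL/cm^3/min (derived; NA when k2 + k3 = 0).
#' @slot converged logical fit-convergence flag.
#' @slot fitInfo list of optimiser diagnostics (may be empty).
#'
#' @export
setClass("KineticParams",
         representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                        vb = "numeric", Ki = "numeric", converged = "logical",
                        fitInfo = "list"),
         prototype(converged = TRUE, fitInfo = list(), Ki = NA_real_))

setValidity("KineticParams", function(object) {
  p <- c(object@K1, object@k2, object@k3, object@vb)
  if (length(p) != 4L) return("K1, k2, k3, vb must each be scalar")
  if (any(!is.finite(p))) return("parameters must be finite")
  if (any(p < -1e-9) || any(p > 1 + 1e-9))
    return("parameters must lie in [0, 1]")
  ktot <- object@k2 + object@k3
  if (ktot > 0 && is.finite(object@Ki)) {
    if (abs(object@Ki - object@K1 * object@k3 / ktot) > 1e-6)
      return("Ki inconsistent with K1*k3/(k2+k3)")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## PhantomSpec / PhantomTruth
## ---------------------------------------------------------------------------

#' Synthetic head-phantom specification
#'
#' All tunable parameters of the dynamic FDG head phantom: the tri-exponential
#' bolus model of the arterial input, venous delay/dispersion, vessel and
#' blood-pool geometry, grey/white-matter kinetics, image resolution, noise
#' level and random seed. See [phantomSpec()] for defaults and units.
#'
#' @export
setClass("PhantomSpec",
         representation(aifParams = "list",
                        veinDelay = "numeric", veinDispersionTau = "numeric",
                        arteryRadius = "numeric", veinRadius = "numeric",
                        daRadius = "numeric",
                        gmParams = "KineticParams", wmParams = "KineticParams",
                        pvParams = "KineticParams",
                        dgParams = "KineticParams",
                        psfFwhm = "numeric", noiseScale = "numeric",
                        gridDim = "integer", voxelSize = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(c(object@arteryRadius, object@veinRadius, object@daRadius) <= 0))
    return("vessel radii must be > 0")
  if (object@veinDelay < 0) return("veinDelay must be >= 0")
  if (object@veinDispersionTau < 0) return("veinDispersionTau must be >= 0")
  if (object@psfFwhm < 0) return("psfFwhm must be >= 0")
  if (object@noiseScale < 0) return("noiseScale must be >= 0")
  if (length(object@gridDim) != 3L || any(object@gridDim < 8L))
    return("gridDim must be three dimensions >= 8")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths (mm)")
  TRUE
})

#' Ground truth emitted alongside a simulated phantom image
#'
#' @slot trueAif frame-averaged arterial input function (label `"truth"`).
#' @slot trueAifFine the same curve on a dense 0.5 s grid.
#' @slot trueVenous frame-averaged delayed/dispersed venous curve.
#' @slot trueVenousFine the venous curve on the dense grid.
#' @slot masks named list of [VoxelMask-class] objects
#'   (`artery`, `vein`, `da`, `gm`, `wm`), pairwise disjoint.
#' @slot daCenter mm coordinates of the descending-aorta cylinder centre.
#' @slot spec the generating [PhantomSpec-class].
#'
#' @export
setClass("PhantomTruth",
         representation(trueAif = "InputFunction",
                        trueAifFine = "InputFunction",
                        trueVenous = "InputFunction",
                        trueVenousFine = "InputFunction",
                        masks = "list", daCenter = "numeric",
                        spec = "PhantomSpec"))

setValidity("PhantomTruth", function(object) {
  keys <- lapply(object@masks, function(m)
    paste(m@coords[, 1], m@coords[, 2], m@coords[, 3]))
  all_keys <- unlist(keys)
  if (anyDuplicated(all_keys) > 0L) return("region masks must be disjoint")
  TRUE
})

## ---------------------------------------------------------------------------
## CohortStats / ClusterResult
## ---------------------------------------------------------------------------

#' Cohort peak/tail statistics
#'
#' `meanPeak` is the mean of the 10 largest detected peak values in a voxel
#' cohort and `meanTail` the mean of the 10 smallest tail values (all values
#' if fewer than 10 are available). These anchor the peak and tail filtering
#' thresholds.
#'
#' @export
setClass("CohortStats",
         representation(meanPeak = "numeric", meanTail = "numeric"))

setValidity("CohortStats", function(object) {
  if (!is.finite(object@meanPeak) || !is.finite(object@meanTail))
    return("statistics must be finite")
  TRUE
})

#' Artery/vein cluster assignment
#'
#' Row-index sets (into the originating TAC matrix) for the arterial and
#' venous clusters, with each cluster's mean time-to-peak in seconds.
#' `arteryTtp <= veinTtp` by construction.
#'
#' @export
setClass("ClusterResult",
         representation(arteryRows = "integer", veinRows = "integer",
                        arteryTtp = "numeric", veinTtp = "numeric"))

setValidity("ClusterResult", function(object) {
  if (length(object@arteryRows) == 0L || length(object@veinRows) == 0L)
    return("both clusters must be non-empty")
  if (length(intersect(object@arteryRows, object@veinRows)) > 0L)
    return("clusters must be disjoint")
  if (object@arteryTtp > object@veinTtp + 1e-9)
    return("artery mean time-to-peak must not exceed the vein's")
  TRUE
})

## ---------------------------------------------------------------------------
## ParametricMap
## ---------------------------------------------------------------------------

#' Voxel-wise kinetic parameter maps
#'
#' 3D grids for K1, k2, k3, vb and Ki (2TCM) plus the Patlak Ki, on the
#' spatial grid of the source image. Voxels outside the mask or with failed
#' fits carry `NA`; `converged` flags fit status per voxel.
#'
#' @slot maps named list of 3D arrays
#'   (`K1`, `k2`, `k3`, `vb`, `Ki2tcm`, `KiPatlak`).
#' @slot converged logical 3D array (`NA` outside the mask).
#'
#' @export
setClass("ParametricMap",
         representation(maps = "list", converged = "array"))

setValidity("ParametricMap", function(object) {
  dims <- unique(lapply(object@maps, dim))
  if (length(dims) != 1L) return("all maps must share one spatial grid")
  if (!identical(dim(object@converged), dims[[1]]))
    return("converged array must match the map grid")
  TRUE
})
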