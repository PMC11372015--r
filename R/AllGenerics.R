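## Accessor generics and show methods.

#' @rdname FrameSchedule-class
#' @param object,x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameSchedule-class
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@start))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameStart", function(x) standardGeneric("frameStart"))

#' @rdname FrameSchedule-class
#' @export
setMethod("frameStart", "FrameSchedule", function(x) x@start)

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))

#' @rdname FrameSchedule-class
#' @export
setMethod("frameDuration", "FrameSchedule", function(x) x@duration)

#' @rdname FrameSchedule-class
#' @export
setGeneric("totalTime", function(x) standardGeneric("totalTime"))

#' @rdname FrameSchedule-class
#' @export
setMethod("totalTime", "FrameSchedule", function(x)
  x@start[nFrames(x)] + x@duration[nFrames(x)])

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, 0-%g s (%.1f min)\n",
              nFrames(object), totalTime(object), totalTime(object) / 60))
  d <- rle(object@duration)
  cat("  blocks:", paste(sprintf("%d x %g s", d$lengths, d$values),
                         collapse = ", "), "\n")
})

#' @rdname DynamicImage-class
#' @param x a `DynamicImage`.
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @rdname DynamicImage-class
#' @export
setMethod("imageValues", "DynamicImage", function(x) x@values)

#' @rdname DynamicImage-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname DynamicImage-class
#' @export
setMethod("voxelSize", "DynamicImage", function(x) x@voxelSize)

#' @rdname DynamicImage-class
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @rdname DynamicImage-class
#' @export
setMethod("schedule", "DynamicImage", function(x) x@schedule)

#' @rdname DynamicImage-class
#' @export
setMethod("schedule", "TACMatrix", function(x) x@schedule)

#' @rdname DynamicImage-class
#' @export
setGeneric("imageFwhm", function(x) standardGeneric("imageFwhm"))

#' @rdname DynamicImage-class
#' @export
setMethod("imageFwhm", "DynamicImage", function(x) x@fwhm)

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("DynamicImage: %d x %d x %d voxels x %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm; effective FWHM: %.2f mm\n",
              paste(format(object@voxelSize), collapse = " x "), object@fwhm))
})

#' @rdname VoxelMask-class
#' @param x a `VoxelMask` or `TACMatrix`.
#' @export
setGeneric("maskCoords", function(x) standardGeneric("maskCoords"))

#' @rdname VoxelMask-class
#' @export
setMethod("maskCoords", "VoxelMask", function(x) x@coords)

#' @rdname VoxelMask-class
#' @export
setMethod("maskCoords", "TACMatrix", function(x) x@coords)

#' @rdname VoxelMask-class
#' @export
setGeneric("maskSize", function(x) standardGeneric("maskSize"))

#' @rdname VoxelMask-class
#' @export
setMethod("maskSize", "VoxelMask", function(x) nrow(x@coords))

setMethod("show", "VoxelMask", function(object)
  cat(sprintf("VoxelMask: %d voxels\n", nrow(object@coords))))

#' @rdname TACMatrix-class
#' @param x a `TACMatrix`.
#' @export
setGeneric("tacValues", function(x) standardGeneric("tacValues"))

#' @rdname TACMatrix-class
#' @export
setMethod("tacValues", "TACMatrix", function(x) x@activities)

setMethod("show", "TACMatrix", function(object)
  cat(sprintf("TACMatrix: %d voxels x %d frames\n",
              nrow(object@activities), ncol(object@activities))))

#' @rdname InputFunction-class
#' @param x an `InputFunction`.
#' @export
setGeneric("ifTimes", function(x) standardGeneric("ifTimes"))

#' @rdname InputFunction-class
#' @export
setMethod("ifTimes", "InputFunction", function(x) x@times)

#' @rdname InputFunction-class
#' @export
setGeneric("ifValues", function(x) standardGeneric("ifValues"))

#' @rdname InputFunction-class
#' @export
setMethod("ifValues", "InputFunction", function(x) x@values)

#' @rdname InputFunction-class
#' @export
setGeneric("ifLabel", function(x) standardGeneric("ifLabel"))

#' @rdname InputFunction-class
#' @export
setMethod("ifLabel", "InputFunction", function(x) x@label)

setMethod("show", "InputFunction", function(object) {
  cat(sprintf("InputFunction [%s]: %d points, %g-%g s, peak %.3g kBq/mL\n",
              object@label, length(object@times), min(object@times),
              max(object@times), max(object@values)))
})

#' @rdname KineticParams-class
#' @param x a `KineticParams`.
#' @export
setGeneric("kineticVector", function(x) standardGeneric("kineticVector"))

#' @rdname KineticParams-class
#' @export
setMethod("kineticVector", "KineticParams", function(x)
  c(K1 = x@K1, k2 = x@k2, k3 = x@k3, vb = x@vb, Ki = x@Ki))

setMethod("show", "KineticParams", function(object) {
  cat(sprintf(paste0("KineticParams: K1=%.4f mL/cm3/min, k2=%.4f, ",
                     "k3=%.4f 1/min, vb=%.4f, Ki=%.4f%s\n"),
              object@K1, object@k2, object@k3, object@vb, object@Ki,
              if (object@converged) "" else " [not converged]"))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(paste0("ClusterResult: %d arterial rows (TTP %.1f s), ",
                     "%d venous rows (TTP %.1f s)\n"),
              length(object@arteryRows), object@arteryTtp,
              length(object@veinRows), object@veinTtp))
})

setMethod("show", "CohortStats", function(object)
  cat(sprintf("CohortStats: meanPeak=%.3g, meanTail=%.3g kBq/mL\n",
              object@meanPeak, object@meanTail)))

setMethod("show", "PhantomTruth", function(object) {
  sz <- vapply(object@masks, function(m) nrow(m@coords), integer(1))
  cat("PhantomTruth:\n  region sizes:",
      paste(sprintf("%s=%d", names(sz), sz), collapse = ", "), "\n")
})

setMethod("show", "ParametricMap", function(object) {
  ok <- sum(object@converged, na.rm = TRUE)
  n <- sum(!is.na(object@converged))
  cat(sprintf("ParametricMap: %s; %d/%d voxels converged\n",
              paste(names(object@maps), collapse = ", "), ok, n))
})
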