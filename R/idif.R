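## IDIF formation: cluster averages, multi-threshold averaging, time-period
## AUC adjudication, peak alignment, the hybrid automatic IDIF, and the
## descending-aorta reference VOI.

#' Average a cluster of voxel curves into an input function
#'
#' Pointwise mean across the selected rows, on the frame mid-time grid.
#'
#' @param tacs a [TACMatrix-class].
#' @param rows non-empty integer vector of row indices.
#' @param label curve label (default `"artery"`).
#' @return an [InputFunction-class].
#' @export
averageCluster <- function(tacs, rows, label = "artery") {
  stopifnot(is(tacs, "TACMatrix"))
  if (length(rows) == 0L) stop("cannot average an empty cluster")
  vals <- colMeans(tacs@activities[rows, , drop = FALSE])
  new("InputFunction", times = frameMidtimes(tacs@schedule),
      values = vals, label = label)
}

#' Multi-threshold arterial and venous input functions
#'
#' Runs filter -> cluster -> label -> average at each peak-threshold level in
#' `a1Set` and averages the resulting arterial input functions pointwise
#' (likewise the venous ones). Averaging across the 0.4-0.6 threshold levels
#' generalises the extraction across subjects better than any single level.
#'
#' @param tacs a [TACMatrix-class].
#' @param peaks optional data.frame from [detectPeaks()]; computed if `NULL`.
#' @param tails optional tail vector; computed if `NULL`.
#' @param a1Set peak threshold levels (default `c(0.4, 0.5, 0.6)`).
#' @param a2 tail threshold level (default 0.9).
#' @return list with `artery` and `vein` ([InputFunction-class]s averaged
#'   over the levels) and `levels`, a per-level list of
#'   [ClusterResult-class]s. Errors name the first level at which filtering
#'   or clustering fails.
#' @export
multiThresholdIdif <- function(tacs, peaks = NULL, tails = NULL,
                               a1Set = c(0.4, 0.5, 0.6), a2 = 0.9) {
  stopifnot(is(tacs, "TACMatrix"))
  if (is.null(peaks)) peaks <- detectPeaks(tacs)
  if (is.null(tails)) tails <- tailValues(tacs)
  stats <- cohortPeakTailStats(peaks, tails)
  arteries <- veins <- list()
  levels <- list()
  for (a1 in a1Set) {
    rows <- suppressWarnings(filterCandidates(peaks, tails, stats, a1, a2))
    if (length(rows) < 2L)
      stop(sprintf("fewer than 2 curves survive filtering at a1=%.2g", a1))
    cl <- clusterTwo(tacs, rows)
    res <- labelArteryVein(cl, peaks, tails)
    arteries[[length(arteries) + 1L]] <-
      averageCluster(tacs, res@arteryRows, "artery")
    veins[[length(veins) + 1L]] <-
      averageCluster(tacs, res@veinRows, "vein")
    levels[[sprintf("a1=%.2g", a1)]] <- res
  }
  avg <- function(ifs, label) {
    vals <- rowMeans(vapply(ifs, function(f) f@values,
                            numeric(length(ifs[[1]]@values))))
    new("InputFunction", times = ifs[[1]]@times, values = vals,
        label = label)
  }
  list(artery = avg(arteries, "artery"), vein = avg(veins, "vein"),
       levels = levels)
}

#' Partition the acquisition into the seven adjudication periods
#'
#' T1 runs from 0 to 20 s after the identified bolus peak (capturing the
#' highest point of the curve), T2-T6 are successive 10-min windows, and T7
#' extends to the end of the acquisition.
#'
#' @param peakTime bolus peak time (s).
#' @param total acquisition end (s).
#' @return numeric vector of 8 boundaries (s), `[0, ..., total]`.
#' @export
timePeriods <- function(peakTime, total) {
  if (peakTime + 20 >= total)
    stop("peak must occur more than 20 s before the end of the acquisition")
  b <- c(0, peakTime + 20 + 600 * (0:5), total)
  if (any(diff(b) <= 0))
    stop("acquisition too short for seven time periods")
  b
}

#' Per-period AUC errors of a candidate curve against a reference
#'
#' Both curves are interpolated to a common 2 s grid with the period
#' boundaries inserted as grid points (so period AUCs sum exactly to the
#' total), integrated by the trapezoidal rule over each period, and compared
#' as percentage errors `100 * (AUC - AUCref) / AUCref`.
#'
#' @param candidate,reference [InputFunction-class]s covering all periods.
#' @param periods boundary vector from [timePeriods()].
#' @return numeric vector of 7 percentage errors.
#' @export
periodAucErrors <- function(candidate, reference, periods) {
  stopifnot(is(candidate, "InputFunction"), is(reference, "InputFunction"))
  grid <- sort(unique(c(seq(periods[1], periods[length(periods)],
                            by = .CWT_DT), periods)))
  est <- .ifOnGrid(candidate, grid)
  ref <- .ifOnGrid(reference, grid)
  ciE <- .cumtrapz(grid, est)
  ciR <- .cumtrapz(grid, ref)
  bi <- match(periods, grid)
  aucE <- diff(ciE[bi]); aucR <- diff(ciR[bi])
  if (any(aucR == 0)) stop("reference AUC is zero in at least one period")
  100 * (aucE - aucR) / aucR
}

#' Align the venous peak to the arterial peak
#'
#' Detects both peaks, shifts the venous time axis backwards by the
#' time-to-peak difference, and discards any part of the shifted curve before
#' t = 0. Values are unchanged.
#'
#' @param arteryIf,veinIf [InputFunction-class]s with detectable peaks.
#' @return the shifted venous [InputFunction-class], with attribute `shift`
#'   (seconds the vein was advanced).
#' @export
alignPeaks <- function(arteryIf, veinIf) {
  pa <- cwtPeakDetect(arteryIf@values, arteryIf@times)
  pv <- cwtPeakDetect(veinIf@values, veinIf@times)
  if (!pa$found || !pv$found)
    stop("no detectable peak on the arterial or venous curve")
  shift <- pv$peakTime - pa$peakTime
  t <- veinIf@times - shift
  keep <- t >= 0
  out <- new("InputFunction", times = t[keep], values = veinIf@values[keep],
             label = veinIf@label)
  attr(out, "shift") <- shift
  out
}

#' Form the hybrid automatic input function
#'
#' Combines the initial arterial peak with the venous tail: both curves are
#' interpolated to a uniform 2 s grid, the venous curve is advanced so the
#' peaks align, arterial values are used up to the peak and venous values
#' after it, the 2 grid points (4 s) on each side of the junction are
#' replaced by the mean of the two curves to remove the step, and the result
#' is resampled to the original frame mid-times.
#'
#' @param arteryIf,veinIf [InputFunction-class]s (typically the
#'   multi-threshold averages).
#' @param sched optional [FrameSchedule-class] for the output grid; defaults
#'   to the arterial curve's own times.
#' @return an [InputFunction-class] labelled `"auto"`, with attribute
#'   `fine` holding the pre-resampling 2 s-grid curve.
#' @export
formIdifAuto <- function(arteryIf, veinIf, sched = NULL) {
  grid <- .uniformGrid(arteryIf@times)
  art <- .ifOnGrid(arteryIf, grid)
  veinAligned <- alignPeaks(arteryIf, veinIf)
  ven <- .ifOnGrid(veinAligned, grid)
  pa <- cwtPeakDetect(arteryIf@values, arteryIf@times)
  j <- which.min(abs(grid - pa$peakTime))
  out <- ifelse(seq_along(grid) <= j, art, ven)
  halo <- setdiff(intersect(c(j - 2L, j - 1L, j + 1L, j + 2L),
                            seq_along(grid)), j)
  out[halo] <- (art[halo] + ven[halo]) / 2
  fine <- new("InputFunction", times = grid, values = out, label = "auto")
  times <- if (is.null(sched)) arteryIf@times else frameMidtimes(sched)
  res <- new("InputFunction", times = times,
             values = .interp(grid, out, times), label = "auto")
  attr(res, "fine") <- fine
  res
}

#' Descending-aorta reference input function
#'
#' Per-frame mean over the voxels whose centres fall inside a cylindrical
#' volume of interest (default 10 mm diameter x 10 mm length) placed over
#' the lumen of a large blood pool. A blood pool this size is essentially
#' immune to partial volume effects at clinical PET resolutions, which is
#' what makes it the reference.
#'
#' @param image a [DynamicImage-class].
#' @param center mm coordinates (x, y, z) of the cylinder centre.
#' @param diameter,length cylinder size (mm).
#' @param axis cylinder axis (1, 2 or 3; default 3 = z).
#' @return an [InputFunction-class] labelled `"reference_da"`.
#' @export
referenceDaIdif <- function(image, center, diameter = 10, length = 10,
                            axis = 3L) {
  stopifnot(is(image, "DynamicImage"), length(center) == 3L)
  d <- dim(image@values)
  vs <- image@voxelSize
  if (any(center - c(0, 0, 0) < 0) ||
      any(center > d[1:3] * vs))
    stop("cylinder centre outside the image grid")
  ax <- as.integer(axis)
  rad <- setdiff(1:3, ax)
  cc <- lapply(1:3, function(k) (seq_len(d[k]) - 0.5) * vs[k])
  r2 <- outer((cc[[rad[1]]] - center[rad[1]])^2,
              (cc[[rad[2]]] - center[rad[2]])^2, "+")
  inRad <- r2 <= (diameter / 2)^2
  inAx <- abs(cc[[ax]] - center[ax]) <= length / 2
  if (min(center[rad] - diameter / 2) < 0 ||
      any(center[rad] + diameter / 2 > d[rad] * vs[rad]) ||
      center[ax] - length / 2 < 0 || center[ax] + length / 2 > d[ax] * vs[ax])
    stop("cylinder extends outside the image grid")
  sel <- array(FALSE, d[1:3])
  idx <- which(inRad, arr.ind = TRUE)
  if (nrow(idx) == 0L || !any(inAx)) stop("cylinder contains no voxel centre")
  for (k in which(inAx)) {
    co <- matrix(0L, nrow(idx), 3)
    co[, rad[1]] <- idx[, 1]; co[, rad[2]] <- idx[, 2]; co[, ax] <- k
    sel[co] <- TRUE
  }
  nvox <- prod(d[1:3])
  vmat <- matrix(image@values, nvox, d[4])
  vals <- colMeans(vmat[which(sel), , drop = FALSE])
  new("InputFunction", times = frameMidtimes(image@schedule),
      values = vals, label = "reference_da")
}

#' End-to-end automatic IDIF extraction
#'
#' Convenience wrapper running the full pipeline on a dynamic image: brain
#' masking, TAC extraction, wavelet peak detection, multi-threshold
#' filtering/clustering, and hybrid IDIF formation.
#'
#' @param image a [DynamicImage-class].
#' @param a1Set,a2 threshold levels, see [multiThresholdIdif()].
#' @param axialExtent brain coverage for [brainMask()] (mm).
#' @return list with `idif` (the `"auto"` [InputFunction-class]), `artery`,
#'   `vein`, `levels` (per-level [ClusterResult-class]s), `tacs`, `peaks`
#'   and `tails`.
#' @export
extractIdifAuto <- function(image, a1Set = c(0.4, 0.5, 0.6), a2 = 0.9,
                            axialExtent = 200) {
  mask <- brainMask(image, axialExtent)
  tacs <- extractTacMatrix(image, mask)
  peaks <- detectPeaks(tacs)
  tails <- tailValues(tacs)
  mt <- multiThresholdIdif(tacs, peaks, tails, a1Set, a2)
  idif <- formIdifAuto(mt$artery, mt$vein, sched = image@schedule)
  list(idif = idif, artery = mt$artery, vein = mt$vein, levels = mt$levels,
       tacs = tacs, peaks = peaks, tails = tails)
}
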