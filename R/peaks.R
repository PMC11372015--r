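## Shape identification: continuous-wavelet-transform peak detection per TAC
## and cohort peak/tail statistics.

#' Wavelet-based peak detection for one activity curve
#'
#' Resamples the curve to a uniform 2 s grid, computes its continuous wavelet
#' transform with the real Morlet wavelet over integer scales 1-100, and
#' takes as candidates the time-local maxima of the strongest-scale
#' coefficient profile whose magnitude exceeds half the curve's maximum
#' coefficient. Each candidate is refined to the nearby curve maximum and the
#' candidate with the largest curve value is reported (earliest time on
#' ties). Curves without structure (e.g. constants) yield `found = FALSE`.
#'
#' @param values activity curve (kBq/mL), at least 8 samples, finite.
#' @param times sample times (s), strictly increasing.
#' @param threshold relative significance threshold for wavelet coefficients
#'   (default 0.5).
#' @return list with `found` (logical), `peakTime` (s) and `peakValue`
#'   (kBq/mL); the latter two are `NA` when no peak is found.
#' @export
cwtPeakDetect <- function(values, times, threshold = 0.5) {
  if (length(values) < 8L) stop("curve must have at least 8 samples")
  if (any(!is.finite(values)) || any(!is.finite(times)))
    stop("curve and times must be finite")
  if (length(values) != length(times) || any(diff(times) <= 0))
    stop("times must be strictly increasing and match the curve length")
  grid <- .uniformGrid(times)
  xg <- .interp(times, values, grid)
  coefs <- .cwtCoefs(matrix(xg, ncol = 1))
  env <- .coefEnvelope(coefs, length(grid))[, 1]
  .pickPeak(env, xg, grid, threshold)
}

#' Peak detection for every row of a TAC matrix
#'
#' Cohort-scale version of [cwtPeakDetect()]. Because the resampling from
#' frame mid-times to the uniform analysis grid is linear, the wavelet
#' transform of every voxel reduces to one precomputed linear operator
#' applied to the frame values, evaluated blockwise.
#'
#' @param tacs a [TACMatrix-class].
#' @param threshold relative coefficient significance threshold.
#' @param blockSize voxels per operator block (memory/speed trade-off).
#' @return data.frame with one row per voxel: `row`, `found`, `peakTime`,
#'   `peakValue`.
#' @export
detectPeaks <- function(tacs, threshold = 0.5, blockSize = 256L) {
  stopifnot(is(tacs, "TACMatrix"))
  mid <- frameMidtimes(tacs@schedule)
  op <- .cwtOperator(mid)
  grid <- op$grid
  T <- length(grid)
  M <- nrow(tacs@activities)
  found <- logical(M); pt <- pv <- rep(NA_real_, M)
  # interpolated curves, needed for refinement/value lookup
  for (b0 in seq(1L, M, by = blockSize)) {
    rows <- b0:min(M, b0 + blockSize - 1L)
    A <- t(tacs@activities[rows, , drop = FALSE])
    coefs <- op$W %*% A
    env <- .coefEnvelope(coefs, T)
    XG <- apply(A, 2, function(v) .interp(mid, v, grid))
    for (q in seq_along(rows)) {
      p <- .pickPeak(env[, q], XG[, q], grid, threshold)
      found[rows[q]] <- p$found
      pt[rows[q]] <- p$peakTime
      pv[rows[q]] <- p$peakValue
    }
  }
  data.frame(row = seq_len(M), found = found, peakTime = pt, peakValue = pv)
}

#' Tail value of an activity curve
#'
#' Duration-weighted mean of the final two frames' activities (the 55-65 min
#' window on a standard 65-min schedule); for equal final durations this is
#' the plain mean.
#'
#' @param values activity curve, one value per frame.
#' @param sched the [FrameSchedule-class] (>= 2 frames).
#' @return tail activity (kBq/mL).
#' @export
tailValue <- function(values, sched) {
  stopifnot(is(sched, "FrameSchedule"))
  n <- nFrames(sched)
  if (n < 2L) stop("schedule must have at least 2 frames")
  if (length(values) != n) stop("curve length must equal the frame count")
  i <- c(n - 1L, n)
  sum(values[i] * sched@duration[i]) / sum(sched@duration[i])
}

#' @rdname tailValue
#' @param tacs a [TACMatrix-class].
#' @return `tailValues` returns one tail per voxel row.
#' @export
tailValues <- function(tacs) {
  stopifnot(is(tacs, "TACMatrix"))
  sched <- tacs@schedule
  n <- nFrames(sched)
  i <- c(n - 1L, n)
  as.numeric(tacs@activities[, i, drop = FALSE] %*%
               (sched@duration[i] / sum(sched@duration[i])))
}

#' Cohort peak and tail statistics
#'
#' `meanPeak` averages the 10 largest detected peak values and `meanTail`
#' the 10 smallest tails (all values when fewer than 10 are available);
#' averaging the extremes rather than taking the single largest peak or
#' smallest tail damps the influence of noise. Curves whose peak detector
#' found nothing are excluded from the peak ranking.
#'
#' @param peaks data.frame from [detectPeaks()] (columns `found`,
#'   `peakValue`), or a numeric vector of peak values.
#' @param tails numeric vector of tail values.
#' @param k number of extremes averaged (default 10).
#' @return a [CohortStats-class].
#' @export
cohortPeakTailStats <- function(peaks, tails, k = 10L) {
  pv <- if (is.data.frame(peaks)) peaks$peakValue[peaks$found] else
    peaks[is.finite(peaks)]
  if (length(pv) == 0L) stop("no curve with a detected peak")
  if (length(tails) == 0L) stop("no tail values supplied")
  topP <- sort(pv, decreasing = TRUE)[seq_len(min(k, length(pv)))]
  lowT <- sort(tails)[seq_len(min(k, length(tails)))]
  new("CohortStats", meanPeak = mean(topP), meanTail = mean(lowT))
}
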