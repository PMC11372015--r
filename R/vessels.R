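## Filtering of non-AIF-shaped curves and artery/vein clustering.

#' Filter voxel curves on peak and tail criteria
#'
#' A voxel survives when its detected peak exceeds `(1 - a1) * meanPeak`
#' (discarding tissue curves and heavily partial-volumed vessels, whose
#' peaks are low) and its tail is below `((1 - a2) * meanTail) + meanTail`
#' (discarding curves with high late uptake, i.e. tissue FDG accumulation).
#' Both comparisons are strict. Curves without a detected peak are removed
#' first.
#'
#' @param peaks data.frame from [detectPeaks()].
#' @param tails numeric vector of tail values, one per row.
#' @param stats a [CohortStats-class] computed from the same cohort.
#' @param a1 peak threshold level, in (0, 1); larger values loosen the
#'   criterion.
#' @param a2 tail threshold level, in (0, 1); default 0.9 (accept tails up
#'   to 1.1 x meanTail).
#' @return sorted integer vector of surviving row indices; empty results are
#'   flagged with a warning so pipelines fail loudly downstream.
#' @export
filterCandidates <- function(peaks, tails, stats, a1, a2 = 0.9) {
  stopifnot(is(stats, "CohortStats"))
  if (length(a1) != 1L || a1 <= 0 || a1 >= 1) stop("a1 must be in (0, 1)")
  if (length(a2) != 1L || a2 <= 0 || a2 >= 1) stop("a2 must be in (0, 1)")
  if (nrow(peaks) != length(tails))
    stop("peaks and tails must describe the same rows")
  keep <- peaks$found &
    peaks$peakValue > (1 - a1) * stats@meanPeak &
    tails < (1 - a2) * stats@meanTail + stats@meanTail
  rows <- peaks$row[which(keep)]
  if (length(rows) == 0L)
    warning(sprintf("no curve passes filtering at a1=%.2g, a2=%.2g", a1, a2))
  sort(rows)
}

#' Split curves into two clusters by Ward hierarchical clustering
#'
#' Agglomerative hierarchical clustering with Ward linkage on the Euclidean
#' distances between raw activity curves, cut at exactly two clusters.
#' Deterministic, and invariant to the order of the input rows (up to the
#' artery/vein relabelling performed by [labelArteryVein()]).
#'
#' @param tacs a [TACMatrix-class] (or plain matrix of curves).
#' @param rows row indices to cluster (>= 2); defaults to all rows.
#' @return list of two integer vectors of row indices. Degenerate inputs in
#'   which all curves are identical produce a warned singleton-style split
#'   rather than an error.
#' @export
clusterTwo <- function(tacs, rows = NULL) {
  acts <- if (is(tacs, "TACMatrix")) tacs@activities else as.matrix(tacs)
  if (is.null(rows)) rows <- seq_len(nrow(acts))
  if (length(rows) < 2L) stop("need at least 2 curves to cluster")
  dd <- stats::dist(acts[rows, , drop = FALSE])
  if (max(dd) <= 0)
    warning("all curves identical: degenerate two-cluster split")
  hc <- stats::hclust(dd, method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  list(rows[grp == 1], rows[grp == 2])
}

#' Label the two clusters as artery and vein
#'
#' The cluster with the earlier mean time-to-peak is arterial: the bolus
#' reaches brain arteries before the venous sinuses. Mean times-to-peak
#' closer than `tieTol` are treated as equal (time-to-peak is quantised at
#' the 2 s analysis grid) and the tie is broken towards the cluster with the
#' smaller mean tail, since veins and tissue share late tails; a warning is
#' emitted.
#'
#' @param clusters list of two row-index vectors from [clusterTwo()].
#' @param peaks data.frame from [detectPeaks()] covering those rows.
#' @param tails numeric tail vector indexed like `peaks$row`.
#' @param tieTol seconds below which mean times-to-peak count as tied
#'   (default 1, half an early-phase frame).
#' @return a [ClusterResult-class].
#' @export
labelArteryVein <- function(clusters, peaks, tails = NULL, tieTol = 1) {
  stopifnot(is.list(clusters), length(clusters) == 2L)
  if (length(clusters[[1]]) == 0L || length(clusters[[2]]) == 0L)
    stop("both clusters must be non-empty")
  ttp <- vapply(clusters, function(r)
    mean(peaks$peakTime[match(r, peaks$row)]), numeric(1))
  if (abs(ttp[1] - ttp[2]) <= tieTol) {
    if (is.null(tails))
      stop("tied mean times-to-peak but no tails supplied for tie-breaking")
    warning("mean times-to-peak tied; labelling artery by smaller mean tail")
    mt <- vapply(clusters, function(r) mean(tails[r]), numeric(1))
    a <- which.min(mt)
  } else {
    a <- which.min(ttp)
  }
  v <- 3L - a
  new("ClusterResult",
      arteryRows = as.integer(sort(clusters[[a]])),
      veinRows = as.integer(sort(clusters[[v]])),
      arteryTtp = min(ttp[a], ttp[v]), veinTtp = max(ttp[a], ttp[v]))
}
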