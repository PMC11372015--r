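peaksFrame <- function(values, times = NULL, found = TRUE) {
  data.frame(row = seq_along(values), found = found,
             peakTime = if (is.null(times)) seq_along(values) else times,
             peakValue = values)
}

test_that("filtering applies both criteria with strict inequalities", {
  stats <- new("CohortStats", meanPeak = 100, meanTail = 10)
  # peak exactly at the threshold is excluded
  pk <- peaksFrame(c(60, 60 + 1e-9, 80))
  expect_equal(filterCandidates(pk, c(5, 5, 5), stats, a1 = 0.4), c(2L, 3L))
  # a2 = 0.9 accepts tails strictly below 1.1 x meanTail
  pk2 <- peaksFrame(c(90, 90, 90))
  expect_equal(filterCandidates(pk2, c(12, 11, 10.9), stats, 0.4, 0.9), 3L)
  # found = FALSE rows are dropped before filtering
  pk3 <- peaksFrame(c(90, 90), found = c(TRUE, FALSE))
  expect_equal(filterCandidates(pk3, c(5, 5), stats, 0.4), 1L)
  expect_warning(filterCandidates(peaksFrame(10), 50, stats, 0.4),
                 "no curve")
  expect_error(filterCandidates(pk, c(5, 5, 5), stats, a1 = 1.2), "0, 1")
})

test_that("threshold levels order the filtered sets predictably", {
  # raising a1 loosens the peak criterion; raising a2 *tightens* the tail
  # criterion (the accepted band is tails < (2 - a2) * meanTail), so the
  # supersets run in opposite directions
  set.seed(41)
  for (rep in 1:5) {
    pk <- peaksFrame(stats::runif(60, 0, 100))
    tails <- stats::runif(60, 0, 20)
    stats <- cohortPeakTailStats(pk$peakValue, tails)
    for (pair in list(c(0.4, 0.9), c(0.2, 0.5), c(0.5, 0.8))) {
      base <- suppressWarnings(
        filterCandidates(pk, tails, stats, pair[1], pair[2]))
      a1up <- suppressWarnings(
        filterCandidates(pk, tails, stats, pair[1] + 0.3, pair[2]))
      a2dn <- suppressWarnings(
        filterCandidates(pk, tails, stats, pair[1], pair[2] - 0.3))
      expect_true(all(base %in% a1up))
      expect_true(all(base %in% a2dn))
      # brute-force re-derivation of the criterion
      keep <- pk$peakValue > (1 - pair[1]) * stats@meanPeak &
        tails < (2 - pair[2]) * stats@meanTail
      expect_equal(base, which(keep))
    }
  }
})

test_that("Ward clustering separates bolus-like from delayed families", {
  sched <- clinicalSchedule()
  mid <- frameMidtimes(sched)
  set.seed(51)
  early <- t(vapply(1:20, function(i)
    bolusAif(mid) + stats::rnorm(62, 0, 0.4), numeric(62)))
  lateIf <- disperseDelay(trueAifFine(), 6, 3)
  late <- t(vapply(1:20, function(i)
    .ifOnGridExported(lateIf, mid) + stats::rnorm(62, 0, 0.4), numeric(62)))
  acts <- rbind(early, late)
  cl <- clusterTwo(acts)
  grp <- vapply(cl, function(r) all(r <= 20) || all(r > 20), logical(1))
  expect_true(all(grp))                        # perfect 20/20 partition
  expect_equal(sort(c(lengths(cl))), c(20L, 20L))

  # permutation invariance up to label swap
  perm <- sample(40)
  cl2 <- clusterTwo(acts[perm, ])
  sets1 <- lapply(cl, function(r) sort(r))
  sets2 <- lapply(cl2, function(r) sort(perm[r]))
  expect_true(setequal(sets1[[1]], sets2[[1]]) ||
                setequal(sets1[[1]], sets2[[2]]))

  expect_error(clusterTwo(acts[1, , drop = FALSE]), "at least 2")
  expect_warning(clusterTwo(rbind(acts[1, ], acts[1, ])), "identical")
})

test_that("clusters are labelled by time-to-peak with a tail tie-break", {
  pk <- peaksFrame(c(50, 52, 30, 31), times = c(20, 20, 26, 26))
  res <- labelArteryVein(list(1:2, 3:4), pk)
  expect_equal(res@arteryRows, 1:2)
  expect_equal(res@arteryTtp, 20)
  expect_equal(res@veinTtp, 26)
  expect_lte(res@arteryTtp, res@veinTtp)

  # swapped input order gives identical labels
  res2 <- labelArteryVein(list(3:4, 1:2), pk)
  expect_equal(res2@arteryRows, res@arteryRows)

  # tie: smaller mean tail wins, with a warning
  pkTie <- peaksFrame(c(50, 50), times = c(20, 20))
  expect_warning(resT <- labelArteryVein(list(1, 2), pkTie,
                                         tails = c(4, 9)), "tied")
  expect_equal(resT@arteryRows, 1L)
})

test_that("phantom candidates cluster into pure artery and vein groups", {
  ph <- defaultPhantom()
  ex <- extractIdifAuto(ph$image)
  cl <- ex$levels[["a1=0.5"]]
  co <- maskCoords(ex$tacs)
  aKeys <- coordKey(co[cl@arteryRows, , drop = FALSE])
  vKeys <- coordKey(co[cl@veinRows, , drop = FALSE])
  expect_gte(mean(aKeys %in% coordKey(ph$truth@masks$artery)), 0.9)
  expect_gte(mean(vKeys %in% coordKey(ph$truth@masks$vein)), 0.9)
  # measured arterio-venous delay close to the programmed 6 s
  expect_lte(abs((cl@veinTtp - cl@arteryTtp) -
                   ph$truth@spec@veinDelay), 2.5)
})

test_that("arterial core voxels survive filtering on the clean phantom", {
  ph <- cleanPhantom()
  blurred <- blurPsf(ph$image, 3.83)
  tacs <- extractTacMatrix(blurred, brainMask(blurred))
  pk <- detectPeaks(tacs)
  tl <- tailValues(tacs)
  st <- cohortPeakTailStats(pk, tl)
  rows <- filterCandidates(pk, tl, st, a1 = 0.5, a2 = 0.9)
  kept <- coordKey(maskCoords(tacs)[rows, , drop = FALSE])
  # the most central artery voxels (middle slices, disc centres)
  aco <- maskCoords(ph$truth@masks$artery)
  zmid <- range(aco[, 3])[1] + 2:3
  ctr <- aco[aco[, 3] %in% zmid, , drop = FALSE]
  keep <- abs(ctr[, 1] - mean(ctr[, 1])) <= 3 &
    abs(ctr[, 2] - mean(ctr[, 2])) <= 1
  core <- coordKey(ctr[keep, , drop = FALSE])
  expect_gte(mean(core %in% kept), 0.5)
  expect_gt(sum(coordKey(aco) %in% kept), 5)
})
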