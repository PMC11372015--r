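## Synthetic dynamic-FDG head phantom with ground truth: a tri-exponential
## arterial bolus, delayed/dispersed venous blood, 2TCM tissue curves, thin
## arterial and thicker venous vessels, a large descending-aorta blood pool,
## Gaussian PSF blurring and frame-duration-dependent noise.

.PHANTOM_FINE_DT <- 0.5   # s, grid used for ground-truth curves

#' Construct a phantom specification
#'
#' Defaults describe a stylised head on a 64 x 64 x 152 grid of 1.65 mm
#' isotropic voxels: two carotid-like arteries (radius 2.5 mm) running
#' through a low-uptake neck/skull-base band, a venous-sinus-like vein
#' (radius 6 mm) embedded in a deep-grey nucleus inside the grey-matter
#' head section (with a white-matter islet), and an inferior body slab
#' holding a descending-aorta cylinder (radius 13 mm) that provides the
#' large-blood-pool reference; tissue curves are driven by the arterial
#' input through the irreversible 2TCM. The arterial bolus is a tri-exponential
#' (Feng-type) model peaking near 40 s with a peak:60-min-tail ratio of about
#' 20:1; venous blood is the arterial curve delayed 6 s with mild dispersion.
#' The default resolution of 3.83 mm FWHM corresponds to a 3.27 mm scanner
#' PSF combined in quadrature with a 2 mm reconstruction filter.
#'
#' @param aifParams list with `A` (amplitudes: A1 in kBq/mL/s, A2 and A3 in
#'   kBq/mL), `lambda` (three negative rate constants, 1/s) and `t0`
#'   (bolus arrival, s).
#' @param veinDelay arterio-venous transit delay (s).
#' @param veinDispersionTau venous dispersion time constant (s).
#' @param arteryRadius,veinRadius,daRadius vessel radii (mm).
#' @param gmParams,wmParams [KineticParams-class] for grey and white matter
#'   (vb taken from the object).
#' @param pvParams kinetics of the low-uptake perivascular/neck soft tissue
#'   surrounding the arteries.
#' @param dgParams kinetics of the deep-grey nucleus embedding the vein.
#' @param psfFwhm simulated image resolution (mm FWHM).
#' @param noiseScale dimensionless scale of the Gaussian noise model
#'   (sd = noiseScale * sqrt(activity / frame duration)); 0 disables noise.
#' @param gridDim integer(3) grid dimensions.
#' @param voxelSize mm, isotropic scalar or length 3.
#' @param seed integer seed making the simulation reproducible.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(aifParams = list(A = c(12, 3.4, 4.8),
                                         lambda = c(-0.12, -0.00016, -0.002),
                                         t0 = 30),
                        veinDelay = 6, veinDispersionTau = 0.5,
                        arteryRadius = 2.5, veinRadius = 6, daRadius = 13,
                        gmParams = kineticParams(0.173, 0.137, 0.053, 0.05),
                        wmParams = kineticParams(0.061, 0.094, 0.025, 0.03),
                        pvParams = kineticParams(0.02, 0.06, 0.062, 0.02),
                        dgParams = kineticParams(0.08, 0.12, 0.022, 0.04),
                        psfFwhm = sqrt(3.27^2 + 2^2),
                        noiseScale = 0.5,
                        gridDim = c(64L, 64L, 152L),
                        voxelSize = 1.65,
                        seed = 1L) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  new("PhantomSpec", aifParams = aifParams, veinDelay = veinDelay,
      veinDispersionTau = veinDispersionTau, arteryRadius = arteryRadius,
      veinRadius = veinRadius, daRadius = daRadius,
      gmParams = gmParams, wmParams = wmParams, pvParams = pvParams,
      dgParams = dgParams,
      psfFwhm = psfFwhm, noiseScale = noiseScale,
      gridDim = as.integer(gridDim), voxelSize = voxelSize,
      seed = as.integer(seed))
}

#' Tri-exponential arterial bolus model
#'
#' Evaluates the Feng-type arterial input
#' \deqn{C(t) = (A_1 (t-t_0) - A_2 - A_3) e^{\lambda_1 (t-t_0)}
#'            + A_2 e^{\lambda_2 (t-t_0)} + A_3 e^{\lambda_3 (t-t_0)}}
#' for \eqn{t \ge t_0} and 0 before bolus arrival: a single sharp early peak
#' followed by a monotone-trending bi-exponential tail.
#'
#' @param t times (s).
#' @param aifParams parameter list as in [phantomSpec()].
#' @return activity concentrations (kBq/mL), non-negative.
#' @export
bolusAif <- function(t, aifParams = phantomSpec()@aifParams) {
  A <- aifParams$A; lam <- aifParams$lambda; t0 <- aifParams$t0
  if (length(A) != 3L || length(lam) != 3L)
    stop("aifParams must supply three amplitudes and three rate constants")
  if (any(lam >= 0)) stop("exponential rate constants must be negative")
  if (A[1] <= 0) stop("A1 must be > 0")
  s <- pmax(t - t0, 0)
  y <- (A[1] * s - A[2] - A[3]) * exp(lam[1] * s) +
    A[2] * exp(lam[2] * s) + A[3] * exp(lam[3] * s)
  y[t < t0] <- 0
  # reject parameter sets that go negative anywhere in the acquisition span
  chk <- seq(t0, t0 + 3900, by = 0.5)
  v <- (A[1] * (chk - t0) - A[2] - A[3]) * exp(lam[1] * (chk - t0)) +
    A[2] * exp(lam[2] * (chk - t0)) + A[3] * exp(lam[3] * (chk - t0))
  if (any(v < -1e-9))
    stop("bolus parameters produce negative activity on [0, 3900 s]")
  y
}

#' Delay and disperse a blood curve
#'
#' Models venous transit: the curve is shifted by `delay` seconds and then
#' convolved with the unit-area dispersion kernel
#' \eqn{(1/\tau) e^{-t/\tau}}. `tau = 0` reduces to a pure shift. The
#' convolution is computed on a uniform fine grid with an exact recursive
#' exponential filter, so the area under the curve is conserved.
#'
#' @param curve an [InputFunction-class].
#' @param delay transit delay (s), >= 0.
#' @param tau dispersion time constant (s), >= 0.
#' @return an [InputFunction-class] on a uniform grid spanning the input.
#' @export
disperseDelay <- function(curve, delay, tau) {
  stopifnot(is(curve, "InputFunction"))
  if (delay < 0 || tau < 0) stop("delay and tau must be >= 0")
  dts <- diff(curve@times)
  dt <- if (max(dts) - min(dts) < 1e-9) dts[1] else .PHANTOM_FINE_DT
  tg <- seq(curve@times[1], curve@times[length(curve@times)], by = dt)
  # shift: values before the (shifted) start of support are zero
  x <- stats::approx(curve@times + delay, curve@values, xout = tg,
                     yleft = 0, rule = 2)$y
  if (tau > 0) {
    E <- exp(-dt / tau)
    x <- as.numeric(stats::filter((1 - E) * x, E, method = "recursive"))
  }
  new("InputFunction", times = tg, values = x, label = curve@label)
}

## ---------------------------------------------------------------------------
## Geometry helpers (mm coordinates; voxel centre of 0-based index i is
## (i + 0.5) * voxelSize)
## ---------------------------------------------------------------------------

# Anatomy of the phantom, bottom to top along z:
#   * a body slab holding the descending-aorta cylinder inside soft tissue
#     (outside the brain axial coverage, as on a long-axial-FOV scanner);
#   * a neck/skull-base band of low-uptake soft tissue carrying the two
#     carotid-like arteries (real carotids run through tissue whose late
#     uptake is close to blood, which is what lets partially-volumed
#     arterial voxels through the tail filter);
#   * a head band: grey-matter cortex with a white-matter islet and a
#     deep-grey nucleus that embeds the venous sinus (hot surroundings force
#     near-full recovery on the venous voxels the filter accepts).
# Blood never approaches air or sub-threshold tissue closer than the PSF
# support in any direction: partial-volume mixes of blood-dominated signal
# with air have high means but tiny tails and would corrupt the cohort tail
# statistic that anchors the filtering thresholds.
.phantomGeometry <- function(spec) {
  d <- spec@gridDim; vs <- spec@voxelSize
  cx <- d[1] * vs[1] / 2; cy <- d[2] * vs[2] / 2
  xs <- (seq_len(d[1]) - 0.5) * vs[1]
  ys <- (seq_len(d[2]) - 0.5) * vs[2]
  zs <- (seq_len(d[3]) - 0.5) * vs[3]
  headSlices <- (d[3] - 19L):(d[3] - 9L)          # 11 axial slices of head
  neckSlices <- (d[3] - 35L):(d[3] - 20L)         # 16 slices of neck below
  bodySlices <- 1L:16L                            # inferior body slab
  inEllipse <- function(x0, y0, a, b)
    outer((xs - x0)^2 / a^2, (ys - y0)^2 / b^2, "+") <= 1
  inDisc <- function(x0, y0, r) inEllipse(x0, y0, r, r)
  list(
    dim = d, vs = vs, cx = cx, cy = cy, zs = zs,
    headSlices = headSlices, neckSlices = neckSlices,
    bodySlices = bodySlices,
    veinSlices = headSlices[3:8],
    dgSlices = headSlices[1:10],
    arterySlices = neckSlices[7:12],
    head = inEllipse(cx, cy, 13, 12),
    wm = inEllipse(cx - 6.5, cy + 6, 2.3, 1.4),
    dg = inDisc(cx, cy, 10),
    vein = inDisc(cx, cy, spec@veinRadius),
    neck = inEllipse(cx, cy, 15.5, 12.5),
    artery = inDisc(cx - 4.5, cy, spec@arteryRadius) |
      inDisc(cx + 4.5, cy, spec@arteryRadius),
    body = inEllipse(cx, cy, 26, 22),
    da = inDisc(cx, cy, spec@daRadius),
    daCenter = c(cx, cy, mean(zs[1L:16L]))
  )
}

# voxel coordinate matrix (0-based) for a 2D in-plane mask over given slices
.sliceMask <- function(plane, slices, d) {
  ij <- which(plane, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(matrix(integer(0), 0, 3))
  out <- do.call(rbind, lapply(slices, function(k)
    cbind(ij[, 1] - 1L, ij[, 2] - 1L, k - 1L)))
  out
}

## ---------------------------------------------------------------------------
## Phantom construction
## ---------------------------------------------------------------------------

#' Simulate a dynamic FDG head phantom
#'
#' Builds a 4D dynamic image on the schedule's time grid: arterial voxels
#' carry the frame-averaged bolus input, venous voxels the delayed/dispersed
#' venous curve, grey/white matter the irreversible-2TCM forward model with
#' their blood volume fractions, and the descending-aorta cylinder the
#' undistorted arterial input. Each frame is then blurred with an isotropic
#' 3D Gaussian PSF and Gaussian noise with variance proportional to
#' activity / frame duration is added. The simulation is reproducible for a
#' fixed `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param sched a [FrameSchedule-class].
#' @return list with elements `image` (a [DynamicImage-class]) and `truth`
#'   (a [PhantomTruth-class]).
#' @export
buildPhantom <- function(spec, sched) {
  stopifnot(is(spec, "PhantomSpec"), is(sched, "FrameSchedule"))
  g <- .phantomGeometry(spec)
  d <- g$dim
  if (max(g$headSlices) > d[3] || min(g$bodySlices) < 1L)
    stop("phantom geometry exceeds the grid")

  tEnd <- totalTime(sched)
  tFine <- seq(0, tEnd, by = .PHANTOM_FINE_DT)
  aifFine <- bolusAif(tFine, spec@aifParams)
  aifIF <- new("InputFunction", times = tFine, values = aifFine,
               label = "truth")
  venIF <- disperseDelay(aifIF, spec@veinDelay, spec@veinDispersionTau)

  frameAif <- .frameAverage(tFine, aifFine, sched)
  frameVen <- .frameAverage(venIF@times, venIF@values, sched)
  gmCurve <- model2tcmIrr(spec@gmParams, aifIF, sched)
  wmCurve <- model2tcmIrr(spec@wmParams, aifIF, sched)
  pvCurve <- model2tcmIrr(spec@pvParams, aifIF, sched)
  dgCurve <- model2tcmIrr(spec@dgParams, aifIF, sched)

  # disjoint region planes (blood takes priority where regions overlap)
  wmPlane <- g$wm & g$head
  veinPlane <- g$vein & g$head & !wmPlane
  dgPlane <- g$dg & g$head & !wmPlane & !veinPlane
  arteryPlane <- g$artery & g$neck
  daPlane <- g$da & g$body
  bodyPlane <- g$body & !daPlane
  capSlices <- setdiff(g$dgSlices, g$veinSlices)
  gmOnlySlices <- setdiff(g$headSlices, g$dgSlices)
  pvVesselSlices <- g$arterySlices
  pvPlainSlices <- setdiff(g$neckSlices, g$arterySlices)

  regions <- list(
    vein = list(plane = veinPlane, slices = g$veinSlices, curve = frameVen),
    dgCap = list(plane = dgPlane | veinPlane, slices = capSlices,
                 curve = dgCurve),
    dg = list(plane = dgPlane, slices = g$veinSlices, curve = dgCurve),
    gmA = list(plane = g$head & !wmPlane, slices = gmOnlySlices,
               curve = gmCurve),
    gmB = list(plane = g$head & !wmPlane & !g$dg & !veinPlane,
               slices = g$dgSlices, curve = gmCurve),
    wm = list(plane = wmPlane, slices = g$headSlices, curve = wmCurve),
    artery = list(plane = arteryPlane, slices = g$arterySlices,
                  curve = frameAif),
    pvA = list(plane = g$neck & !arteryPlane, slices = pvVesselSlices,
               curve = pvCurve),
    pvB = list(plane = g$neck, slices = pvPlainSlices, curve = pvCurve),
    da = list(plane = daPlane, slices = g$bodySlices, curve = frameAif),
    body = list(plane = bodyPlane, slices = g$bodySlices, curve = pvCurve))

  n <- nFrames(sched)
  nvox <- prod(d)
  vmat <- matrix(0, nvox, n)
  coordSets <- list()
  for (nm in names(regions)) {
    r <- regions[[nm]]
    coords <- .sliceMask(r$plane, r$slices, d)
    lin <- 1L + coords[, 1] + d[1] * (coords[, 2] + d[2] * coords[, 3])
    vmat[lin, ] <- matrix(r$curve, nrow(coords), n, byrow = TRUE)
    coordSets[[nm]] <- coords
  }
  masks <- list(
    artery = .newMask(coordSets$artery),
    vein = .newMask(coordSets$vein),
    gm = .newMask(rbind(coordSets$gmA, coordSets$gmB)),
    wm = .newMask(coordSets$wm),
    dg = .newMask(rbind(coordSets$dg, coordSets$dgCap)),
    pv = .newMask(rbind(coordSets$pvA, coordSets$pvB)),
    da = .newMask(coordSets$da))
  arr <- array(vmat, c(d, n))

  img <- new("DynamicImage", values = arr, voxelSize = spec@voxelSize,
             schedule = sched, fwhm = 0)
  if (spec@psfFwhm > 0) img <- blurPsf(img, spec@psfFwhm)

  if (spec@noiseScale > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec@seed)
    vmat <- matrix(img@values, nvox, n)
    for (f in seq_len(n)) {
      idx <- which(vmat[, f] > 0)
      if (length(idx) == 0L) next
      sd <- spec@noiseScale * sqrt(vmat[idx, f] / sched@duration[f])
      vmat[idx, f] <- vmat[idx, f] + stats::rnorm(length(idx), 0, sd)
    }
    img@values <- array(vmat, c(d, n))
  }

  truth <- new("PhantomTruth",
               trueAif = new("InputFunction", times = frameMidtimes(sched),
                             values = frameAif, label = "truth"),
               trueAifFine = aifIF,
               trueVenous = new("InputFunction",
                                times = frameMidtimes(sched),
                                values = frameVen, label = "truth"),
               trueVenousFine = venIF,
               masks = masks, daCenter = g$daCenter, spec = spec)
  list(image = img, truth = truth)
}

#' Blur a dynamic image with an isotropic Gaussian PSF
#'
#' Convolves every frame with a separable 3D Gaussian kernel of the given
#' FWHM (zero boundary). The image's effective-resolution metadata is updated
#' in quadrature (see [combinedFwhm()]); total counts away from the image
#' boundary are preserved because the kernel is normalised.
#'
#' @param image a [DynamicImage-class].
#' @param extraFwhm FWHM of the additional blur (mm); 0 returns the image
#'   unchanged.
#' @return a blurred [DynamicImage-class].
#' @export
blurPsf <- function(image, extraFwhm) {
  stopifnot(is(image, "DynamicImage"))
  if (length(extraFwhm) != 1L || !is.finite(extraFwhm) || extraFwhm < 0)
    stop("extraFwhm must be a single non-negative FWHM in mm")
  if (extraFwhm == 0) return(image)
  sigma <- extraFwhm / (2 * sqrt(2 * log(2)))
  d <- dim(image@values)
  arr <- image@values
  # restrict work to contiguous axial bands around the non-zero support
  # (blur cannot move signal farther than the kernel half-width)
  half <- ceiling(4 * sigma / image@voxelSize[3])
  nz <- which(apply(arr != 0, 3, any))
  if (length(nz) > 0L) {
    active <- sort(unique(pmin(pmax(
      rep(nz, each = 2 * half + 1L) + rep(-half:half, length(nz)), 1L),
      d[3])))
    runs <- split(active, cumsum(c(1L, diff(active) != 1L)))
  } else runs <- list()
  for (band in runs) {
    sub <- arr[, , band, , drop = FALSE]
    ds <- dim(sub)
    for (ax in 1:3) {
      K <- .gaussKernelMatrix(ds[ax], image@voxelSize[ax], sigma)
      perm <- c(ax, setdiff(1:4, ax))
      a <- aperm(sub, perm)
      dimA <- dim(a)
      a <- K %*% matrix(a, dimA[1])
      dim(a) <- dimA
      sub <- aperm(a, order(perm))
    }
    arr[, , band, ] <- sub
  }
  new("DynamicImage", values = arr, voxelSize = image@voxelSize,
      schedule = image@schedule,
      fwhm = combinedFwhm(c(image@fwhm, extraFwhm)))
}

# dense banded convolution matrix for one axis; columns normalised to unit
# sum so a uniform image stays uniform away from the boundary
.gaussKernelMatrix <- function(n, vs, sigma) {
  half <- max(1L, ceiling(4 * sigma / vs))
  offs <- (-half):half
  w <- exp(-0.5 * (offs * vs / sigma)^2)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq_along(offs)) {
    i <- seq_len(n)
    ii <- i + offs[j]
    ok <- ii >= 1L & ii <= n
    K[cbind(ii[ok], i[ok])] <- K[cbind(ii[ok], i[ok])] + w[j]
  }
  K
}
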