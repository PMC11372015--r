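## Irreversible two-tissue compartment model, bounded LM fitting, the Ki
## macro-parameter, Patlak graphical analysis and parametric maps.
##
## Unit convention: rate constants are per minute (K1 in mL/cm^3/min); all
## public time grids are in seconds and converted internally.

.KIN_FINE_DT <- 2   # s, grid for the model convolution

#' Construct a KineticParams object
#'
#' @param K1,k2,k3,vb rate constants (1/min except vb) in `[0, 1]`.
#' @param converged fit convergence flag.
#' @param fitInfo optional list of optimiser diagnostics.
#' @return a [KineticParams-class] with Ki derived via [kiMacro()] (NA when
#'   `k2 + k3 = 0`).
#' @export
kineticParams <- function(K1, k2, k3, vb, converged = TRUE,
                          fitInfo = list()) {
  ki <- if (k2 + k3 > 0) kiMacro(K1, k2, k3) else NA_real_
  new("KineticParams", K1 = K1, k2 = k2, k3 = k3, vb = vb, Ki = ki,
      converged = converged, fitInfo = fitInfo)
}

#' Net influx rate Ki
#'
#' The macro-parameter of irreversible FDG uptake,
#' \eqn{K_i = K_1 k_3 / (k_2 + k_3)} (mL/cm^3/min): the steady-state rate at
#' which tracer is trapped in tissue.
#'
#' @param K1,k2,k3 rate constants; vectorised.
#' @return Ki, same length as the inputs.
#' @export
kiMacro <- function(K1, k2, k3) {
  if (any(k2 + k3 <= 0)) stop("kiMacro requires k2 + k3 > 0")
  K1 * k3 / (k2 + k3)
}

#' Irreversible 2TCM forward model
#'
#' Total tissue concentration
#' \deqn{C_T(t) = (1 - v_b)\left[\left(\frac{K_1 k_2}{k_2 + k_3}
#'   e^{-(k_2+k_3)t} + \frac{K_1 k_3}{k_2 + k_3}\right) \otimes C_p(t)\right]
#'   + v_b C_b(t)}
#' with whole-blood and plasma concentrations identified
#' (\eqn{C_p \equiv C_b}, no metabolite or haematocrit correction). The
#' convolution is computed on a uniform 2 s grid with a recursive
#' exponential-decay filter (the decaying kernel is propagated exactly per
#' step), and frame values are time-averages of the model over each frame,
#' matching how the scanner reports frames. The limit `k2 + k3 = 0` is
#' handled analytically as \eqn{K_1 \int C_p}.
#'
#' @param params a [KineticParams-class] (rates per minute).
#' @param inputFn the input function (an [InputFunction-class], time in s).
#' @param sched a [FrameSchedule-class]; the model is frame-averaged onto it.
#' @param times alternative output: sample (not frame-average) the model at
#'   these times (s). Exactly one of `sched`, `times` is used.
#' @return modelled activity (kBq/mL), one value per frame or time point.
#' @export
model2tcmIrr <- function(params, inputFn, sched = NULL, times = NULL) {
  stopifnot(is(params, "KineticParams"), is(inputFn, "InputFunction"))
  tEnd <- if (!is.null(sched)) totalTime(sched) else max(times)
  tg <- seq(0, tEnd, by = .KIN_FINE_DT)
  cp <- .ifOnGrid(inputFn, tg)
  ct <- .model2tcmGrid(params, tg, cp)
  if (!is.null(sched)) .frameAverage(tg, ct, sched)
  else .interp(tg, ct, times)
}

# model on an explicit grid (tg in s, cp sampled on tg)
.model2tcmGrid <- function(params, tg, cp) {
  K1 <- params@K1; k2 <- params@k2; k3 <- params@k3; vb <- params@vb
  dtm <- (tg[2] - tg[1]) / 60          # min
  beta <- k2 + k3                       # 1/min
  cumint <- .cumtrapz(tg / 60, cp)      # min * kBq/mL
  if (beta < 1e-12) {
    conv <- K1 * cumint
  } else {
    E <- exp(-beta * dtm)
    # y[i] = E*y[i-1] + dtm*(cp[i] + E*cp[i-1])/2  (trapezoid with exact
    # kernel decay per step)
    drive <- dtm * (cp + E * c(0, cp[-length(cp)])) / 2
    drive[1] <- 0
    y <- as.numeric(stats::filter(drive, E, method = "recursive"))
    conv <- (K1 * k2 / beta) * y + (K1 * k3 / beta) * cumint
  }
  (1 - vb) * conv + vb * cp
}

#' Fit the irreversible 2TCM to a time-activity curve
#'
#' Bounded Levenberg-Marquardt least squares of the frame-averaged forward
#' model against the measured curve: initial values 0.01 for all four
#' parameters, box constraints `[0, 1]`, unweighted residuals, and no
#' smoothing or outlier handling. Non-convergence is flagged on the returned
#' object rather than raised as an error, so voxel-wise mapping can proceed.
#'
#' @param tac measured activity, one value per frame.
#' @param inputFn the input function driving the model.
#' @param sched the [FrameSchedule-class].
#' @param init initial parameter values (K1, k2, k3, vb).
#' @return a [KineticParams-class]; `fitInfo` carries the optimiser status
#'   and residual sum of squares.
#' @export
fit2tcm <- function(tac, inputFn, sched, init = rep(0.01, 4)) {
  stopifnot(is(inputFn, "InputFunction"), is(sched, "FrameSchedule"))
  if (length(tac) != nFrames(sched))
    stop("tac length must equal the number of frames")
  tg <- seq(0, totalTime(sched), by = .KIN_FINE_DT)
  cp <- .ifOnGrid(inputFn, tg)
  resid <- function(p) {
    pr <- new("KineticParams", K1 = p[1], k2 = p[2], k3 = p[3], vb = p[4],
              Ki = NA_real_, converged = TRUE, fitInfo = list())
    .frameAverage(tg, .model2tcmGrid(pr, tg, cp), sched) - tac
  }
  # a conservative initial trust region (factor) keeps the first step from
  # jumping onto the box boundary, where projected LM can stall
  fit <- minpack.lm::nls.lm(par = init, lower = rep(0, 4), upper = rep(1, 4),
                            fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12,
                              factor = 0.1))
  p <- pmin(pmax(fit$par, 0), 1)
  conv <- fit$info %in% 1:4
  kineticParams(p[1], p[2], p[3], p[4], converged = conv,
                fitInfo = list(info = fit$info, message = fit$message,
                               rss = sum(fit$fvec^2), niter = fit$niter))
}

#' Patlak graphical analysis
#'
#' Ordinary least squares of \eqn{C_T(t)/C_p(t)} against
#' \eqn{\int_0^t C_p / C_p(t)} restricted to frames with mid-time at or after
#' `tStar` (default 40 min, ensuring pseudo-equilibrium for FDG). The slope
#' estimates the net influx rate Ki for an irreversible tracer; the intercept
#' absorbs the reversible distribution volume and blood signal.
#'
#' @param tac measured activity, one value per frame.
#' @param inputFn the input function.
#' @param sched the [FrameSchedule-class].
#' @param tStar start of the linear window (s; default 2400 = 40 min).
#' @return list with `Ki` (slope, mL/cm^3/min), `intercept`, and `n` (frames
#'   used).
#' @export
patlakFit <- function(tac, inputFn, sched, tStar = 2400) {
  stopifnot(is(inputFn, "InputFunction"), is(sched, "FrameSchedule"))
  mid <- frameMidtimes(sched)
  use <- which(mid >= tStar)
  if (length(use) < 2L)
    stop("fewer than 2 frames with mid-time at or after tStar")
  tg <- seq(0, totalTime(sched), by = .KIN_FINE_DT)
  cp <- .ifOnGrid(inputFn, tg)
  ci <- .cumtrapz(tg / 60, cp)
  cpMid <- .interp(tg, cp, mid[use])
  ciMid <- .interp(tg, ci, mid[use])
  if (any(cpMid <= 0)) stop("input function must be positive on the window")
  x <- ciMid / cpMid
  y <- tac[use] / cpMid
  fit <- stats::lm.fit(cbind(1, x), y)
  list(Ki = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = length(use))
}

#' Voxel-wise parametric maps
#'
#' Fits the irreversible 2TCM and the Patlak model to every masked voxel and
#' assembles 3D parameter grids. Non-fitted voxels are `NA`, and per-voxel
#' convergence flags are retained rather than silently zero-filling.
#'
#' @param image a [DynamicImage-class].
#' @param mask a [VoxelMask-class].
#' @param inputFn the input function.
#' @param tStar Patlak window start (s).
#' @return a [ParametricMap-class].
#' @export
parametricMaps <- function(image, mask, inputFn, tStar = 2400) {
  tacs <- extractTacMatrix(image, mask)
  sched <- image@schedule
  d <- dim(image@values)[1:3]
  nm <- c("K1", "k2", "k3", "vb", "Ki2tcm", "KiPatlak")
  maps <- stats::setNames(rep(list(array(NA_real_, d)), length(nm)), nm)
  conv <- array(NA, d)
  lin <- 1L + tacs@coords[, 1] + d[1] * (tacs@coords[, 2] +
                                           d[2] * tacs@coords[, 3])
  for (i in seq_len(nrow(tacs@activities))) {
    tac <- tacs@activities[i, ]
    fp <- fit2tcm(tac, inputFn, sched)
    pk <- tryCatch(patlakFit(tac, inputFn, sched, tStar),
                   error = function(e) list(Ki = NA_real_))
    maps$K1[lin[i]] <- fp@K1; maps$k2[lin[i]] <- fp@k2
    maps$k3[lin[i]] <- fp@k3; maps$vb[lin[i]] <- fp@vb
    maps$Ki2tcm[lin[i]] <- fp@Ki
    maps$KiPatlak[lin[i]] <- pk$Ki
    conv[lin[i]] <- fp@converged
  }
  new("ParametricMap", maps = maps, converged = conv)
}
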