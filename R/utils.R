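## Internal numerical helpers: interpolation, integration, the Morlet CWT
## machinery shared by peak detection, and frame averaging.

# Uniform analysis grid (s) used throughout: wavelet analysis, curve
# alignment and AUC evaluation all run on a 2 s grid.
.CWT_DT <- 2
.CWT_SCALES <- 1:100       # integer scales, in samples of the 2 s grid
.CWT_REFLECT <- 500L       # reflection padding, samples
.CWT_NFFT <- 4096L

.interp <- function(times, values, xout) {
  stats::approx(times, values, xout = xout, rule = 2)$y
}

.trapz <- function(x, y) pracma::trapz(x, y)

.cumtrapz <- function(x, y) as.vector(pracma::cumtrapz(x, y))

# 2 s grid spanning a time vector
.uniformGrid <- function(times, dt = .CWT_DT) {
  seq(times[1], times[length(times)], by = dt)
}

## ---------------------------------------------------------------------------
## Morlet CWT
## ---------------------------------------------------------------------------

# Real Morlet wavelet sampled at scale a (in samples). The sampled kernel is
# recentred to zero sum (integer sampling of cos(5t/a) aliases at small
# scales and would otherwise leave a DC response) and L2-normalised by
# 1/sqrt(a).
.morletKernel <- function(a) {
  K <- ceiling(5 * a)
  k <- seq(-K, K)
  psi <- exp(-0.5 * (k / a)^2) * cos(5 * k / a)
  psi <- psi - mean(psi)
  psi / sqrt(a)
}

# Spectra of the padded kernels, cached (scales and fft size are fixed).
.pkgCache <- new.env(parent = emptyenv())

.kernelSpectra <- function() {
  if (!is.null(.pkgCache$kspec)) return(.pkgCache$kspec)
  n <- .CWT_NFFT
  kspec <- matrix(0 + 0i, n, length(.CWT_SCALES))
  for (j in seq_along(.CWT_SCALES)) {
    psi <- .morletKernel(.CWT_SCALES[j])
    K <- (length(psi) - 1L) / 2L
    kp <- numeric(n)
    kp[1:(K + 1L)] <- psi[(K + 1L):(2L * K + 1L)]   # k = 0..K
    kp[(n - K + 1L):n] <- psi[1:K]                   # k = -K..-1
    kspec[, j] <- stats::fft(kp)
  }
  .pkgCache$kspec <- kspec
  kspec
}

# Index vector implementing reflection padding of a length-T signal.
.reflectIndex <- function(T) {
  L <- min(.CWT_REFLECT, T - 1L)
  c(seq(L + 1L, 2L), seq_len(T), seq(T - 1L, T - L))
}

# CWT coefficient block for curves on the uniform grid.
# X: T x m matrix (each column one curve). Returns a (T*S) x m matrix with
# scale-major row blocks: rows (s-1)*T + 1:T hold scale s.
.cwtCoefs <- function(X) {
  X <- as.matrix(X)
  T <- nrow(X); m <- ncol(X)
  ridx <- .reflectIndex(T)
  L <- (length(ridx) - T) / 2L
  Xp <- matrix(0, .CWT_NFFT, m)
  Xp[seq_along(ridx), ] <- X[ridx, , drop = FALSE]
  F <- stats::mvfft(Xp)
  kspec <- .kernelSpectra()
  S <- length(.CWT_SCALES)
  out <- matrix(0, T * S, m)
  keep <- (L + 1L):(L + T)
  for (j in seq_len(S)) {
    C <- Re(stats::mvfft(F * kspec[, j], inverse = TRUE)) / .CWT_NFFT
    out[((j - 1L) * T + 1L):(j * T), ] <- C[keep, , drop = FALSE]
  }
  out
}

# Per-time envelope: maximum coefficient over scales.
.coefEnvelope <- function(coefs, T) {
  S <- nrow(coefs) / T
  m <- ncol(coefs)
  env <- matrix(-Inf, T, m)
  for (j in seq_len(S)) {
    blk <- coefs[((j - 1L) * T + 1L):(j * T), , drop = FALSE]
    env <- pmax(env, blk)
  }
  env
}

# Linear operator mapping frame values (n frames) to CWT coefficients on the
# 2 s grid (scale-major, (T*S) x n). The interpolation from frame midtimes to
# the uniform grid is linear, so the whole transform collapses to one matrix;
# cohort-scale peak detection is then a single BLAS multiply per voxel block.
# Cached per schedule.
.cwtOperator <- function(midtimes) {
  key <- paste0("op_", paste(format(midtimes, digits = 10), collapse = ","))
  hit <- .pkgCache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- .uniformGrid(midtimes)
  n <- length(midtimes)
  # interpolation matrix grid x frames (rule-2 constant extrapolation)
  P <- vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    .interp(midtimes, e, grid)
  }, numeric(length(grid)))
  op <- list(grid = grid, W = .cwtCoefs(P))
  .pkgCache[[key]] <- op
  op
}

## ---------------------------------------------------------------------------
## Candidate selection shared by all peak-detection entry points
## ---------------------------------------------------------------------------

# env: envelope on the grid; xg: curve on the grid. Implements the relative
# significance rule (candidates above half the strongest ridge coefficient),
# refines each candidate to the nearby curve maximum and returns the
# candidate with the largest curve value (earliest time on ties).
.pickPeak <- function(env, xg, grid, threshold = 0.5, refineWin = 15L) {
  none <- list(found = FALSE, peakTime = NA_real_, peakValue = NA_real_)
  cmax <- max(env)
  guard <- 1e-4 * max(abs(xg), 1e-300)
  if (!is.finite(cmax) || cmax <= guard) return(none)
  T <- length(env)
  i <- 2:(T - 1L)
  locmax <- i[env[i] > env[i - 1L] & env[i] >= env[i + 1L]]
  cand <- locmax[env[locmax] > threshold * cmax]
  if (length(cand) == 0L) return(none)
  tt <- vv <- numeric(length(cand))
  for (q in seq_along(cand)) {
    w <- max(1L, cand[q] - refineWin):min(T, cand[q] + refineWin)
    b <- w[which.max(xg[w])]
    tt[q] <- grid[b]; vv[q] <- xg[b]
  }
  best <- order(-vv, tt)[1]
  list(found = TRUE, peakTime = tt[best], peakValue = vv[best])
}

## ---------------------------------------------------------------------------
## Frame averaging of a continuous curve
## ---------------------------------------------------------------------------

# Mean of a sampled curve over each frame of a schedule, by exact trapezoidal
# integration between the frame boundaries (boundaries interpolated on the
# cumulative integral, so unaligned grids are handled).
.frameAverage <- function(t, y, sched) {
  ci <- .cumtrapz(t, y)
  bounds <- c(sched@start, totalTime(sched))
  cb <- .interp(t, ci, bounds)
  diff(cb) / sched@duration
}

# Evaluate an InputFunction on an arbitrary grid (constant extrapolation).
.ifOnGrid <- function(input_fn, grid) {
  .interp(input_fn@times, input_fn@values, grid)
}
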