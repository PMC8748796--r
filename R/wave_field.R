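#' WaveField: per-sample, per-node phase gradients, speeds and directions
#'
#' Result container for [waveField()]. `gx`/`gy` hold the fitted spatial
#' gradient of relative phase (rad/mm); `speeds` the propagation speed
#' |d(theta)/dt| / |grad| in m/s; `dirX`/`dirY` the unit propagation
#' direction (from phase-leading to phase-lagging regions). Entries are NA
#' where the local fit is degenerate or the gradient falls below the
#' near-synchrony threshold.
#'
#' @slot gx,gy samples x nodes gradient components, rad/mm.
#' @slot speeds samples x nodes propagation speeds, m/s.
#' @slot dirX,dirY samples x nodes unit propagation direction components.
#' @slot windowSigma Gaussian window standard deviation, mm.
#' @export
setClass("WaveField",
  representation(gx = "matrix", gy = "matrix", speeds = "matrix",
                 dirX = "matrix", dirY = "matrix", windowSigma = "numeric"))

setMethod("show", "WaveField", function(object) {
  cat("WaveField:", nrow(object@gx), "samples x", ncol(object@gx), "nodes\n")
  sp <- object@speeds[is.finite(object@speeds)]
  if (length(sp)) {
    cat(sprintf("  speed: median %.2f m/s (IQR %.2f-%.2f), %d valid estimates\n",
                stats::median(sp), stats::quantile(sp, 0.25),
                stats::quantile(sp, 0.75), length(sp)))
  }
})

# Circular-linear plane fit at one node: maximise the Gaussian-weighted
# resultant |sum_i w_i exp(i(theta_i - a . dx_i))| over gradient vectors a.
# Coarse grid (the objective has local optima under phase wrapping), then
# BFGS refinement with the analytic gradient of |Z|^2.
.clFitRefine <- function(a0, cz, dx) {
  fn <- function(a) {
    z <- sum(cz * exp(-1i * (dx %*% a)))
    -Re(z * Conj(z))
  }
  gr <- function(a) {
    e <- exp(-1i * (dx %*% a))
    z <- sum(cz * e)
    dz1 <- sum(cz * e * (-1i * dx[, 1]))
    dz2 <- sum(cz * e * (-1i * dx[, 2]))
    -2 * c(Re(Conj(z) * dz1), Re(Conj(z) * dz2))
  }
  stats::optim(a0, fn, gr, method = "BFGS",
               control = list(reltol = 1e-12, maxit = 200))$par
}

#' Local phase gradient by circular-linear regression
#'
#' For each node, fits a local plane wave theta'(x) ~ phi0 + a . (x - x_j)
#' to the relative phases of same-hemisphere neighbours under a Gaussian
#' spatial window, by maximising the weighted mean resultant length. The
#' circular objective makes the fit immune to phase wrapping. Nodes with a
#' degenerate neighbourhood (fewer than 3 effective neighbours, or
#' collinear ones) get NA.
#'
#' @param map a \code{SurfaceMap}.
#' @param relPhasesSnapshot numeric vector of relative phases, one per node.
#' @param windowSigma Gaussian window standard deviation, mm (default 20).
#' @param gridMax half-width of the coarse search box in gradient space,
#'   rad/mm (default 0.25; at 10 Hz this spans speeds down to well below
#'   the 1 m/s floor).
#' @param gridN coarse grid points per axis (default 41).
#' @return nodes x 2 matrix of gradient vectors a, rad/mm.
#' @export
phaseGradient <- function(map, relPhasesSnapshot, windowSigma = 20,
                          gridMax = 0.25, gridN = 41L) {
  out <- phaseGradientField(map, matrix(relPhasesSnapshot, nrow = 1),
                            windowSigma = windowSigma, gridMax = gridMax,
                            gridN = gridN)
  cbind(gx = out$gx[1, ], gy = out$gy[1, ])
}

#' Phase gradients for a whole stack of snapshots
#'
#' Vectorised form of [phaseGradient()]: the per-node neighbourhood and
#' Gaussian weights are fixed across samples, so the coarse grid search is
#' evaluated for all samples at once before per-sample refinement.
#'
#' @param map a \code{SurfaceMap}.
#' @param relPhaseMatrix samples x nodes matrix of relative phases.
#' @inheritParams phaseGradient
#' @return list with `gx` and `gy`, samples x nodes matrices (rad/mm).
#' @export
phaseGradientField <- function(map, relPhaseMatrix, windowSigma = 20,
                               gridMax = 0.25, gridN = 41L) {
  x <- mapCoords(map)
  hemi <- hemispheres(map)
  n <- nrow(x)
  stopifnot(ncol(relPhaseMatrix) == n)
  S <- nrow(relPhaseMatrix)
  ax <- seq(-gridMax, gridMax, length.out = gridN)
  grid <- as.matrix(expand.grid(ax, ax))
  gx <- matrix(NA_real_, S, n); gy <- matrix(NA_real_, S, n)
  for (j in seq_len(n)) {
    same <- which(hemi == hemi[j])
    dx <- sweep(x[same, , drop = FALSE], 2, x[j, ])
    d2 <- rowSums(dx^2)
    w <- exp(-d2 / (2 * windowSigma^2))
    keep <- w > 1e-4
    if (sum(keep & same != j) < 3) next
    dx <- dx[keep, , drop = FALSE]; w <- w[keep]; idx <- same[keep]
    # collinearity: weighted second-moment matrix must be well-conditioned
    m2 <- crossprod(dx * sqrt(w))
    ev <- eigen(m2, symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] < 1e-8 * ev[1]) next
    ph <- relPhaseMatrix[, idx, drop = FALSE]
    cz <- exp(1i * ph) * rep(w, each = S)        # S x m weighted phasors
    shift <- exp(-1i * tcrossprod(dx, grid))     # m x candidates
    res <- Mod(cz %*% shift)                     # S x candidates resultants
    best <- max.col(res, ties.method = "first")
    for (s in seq_len(S)) {
      a <- .clFitRefine(grid[best[s], ], cz[s, ], dx)
      gx[s, j] <- a[1]; gy[s, j] <- a[2]
    }
  }
  list(gx = gx, gy = gy)
}

#' Propagation speed from a gradient and an instantaneous rate
#'
#' Constant-phase contours of a plane wave move at |d(theta)/dt| / |grad|,
#' from phase-leading toward phase-lagging regions, i.e. along -grad when
#' the phase is advancing. Gradients below `gradFloor` mark a
#' near-synchronous patch: speed is undefined there (NA).
#'
#' @param grad length-2 gradient vector (or n x 2 matrix), rad/mm.
#' @param instRate instantaneous phase rate d(theta)/dt, rad/s (vector of
#'   length n for the matrix form).
#' @param gradFloor minimum usable |grad|, rad/mm (default 1e-4).
#' @return list with `speed` (m/s) and `dir` (unit 2-vector rows).
#' @export
waveSpeed <- function(grad, instRate, gradFloor = 1e-4) {
  g <- if (is.matrix(grad)) grad else matrix(grad, nrow = 1)
  gn <- sqrt(rowSums(g^2))
  ok <- is.finite(gn) & gn >= gradFloor
  speed <- ifelse(ok, abs(instRate) / gn / 1000, NA_real_)
  dir <- -g / gn * sign(instRate)
  dir[!ok, ] <- NA_real_
  list(speed = speed, dir = dir)
}

#' Full wave field of a trajectory
#'
#' Runs the circular-linear gradient fit on every retained snapshot and
#' derives propagation speeds and unit directions from the model's
#' instantaneous phase rates.
#'
#' @param map a \code{SurfaceMap}.
#' @param traj a \code{PhaseTrajectory}.
#' @inheritParams phaseGradient
#' @param gradFloor minimum usable |grad| for a speed estimate, rad/mm.
#' @return a \code{WaveField}.
#' @export
waveField <- function(map, traj, windowSigma = 20, gridMax = 0.25,
                      gridN = 41L, gradFloor = 1e-4) {
  g <- phaseGradientField(map, relPhases(traj), windowSigma = windowSigma,
                          gridMax = gridMax, gridN = gridN)
  rate <- instRates(traj)
  gn <- sqrt(g$gx^2 + g$gy^2)
  ok <- is.finite(gn) & gn >= gradFloor
  speeds <- ifelse(ok, abs(rate) / gn / 1000, NA_real_)
  sgn <- sign(rate)
  dirX <- ifelse(ok, -g$gx / gn * sgn, NA_real_)
  dirY <- ifelse(ok, -g$gy / gn * sgn, NA_real_)
  new("WaveField", gx = g$gx, gy = g$gy, speeds = speeds,
      dirX = dirX, dirY = dirY, windowSigma = windowSigma)
}

#' Mean propagation direction per node
#'
#' Circular mean and circular standard deviation of the per-sample
#' propagation directions at each node. Nodes whose direction distribution
#' is balanced (resultant below `tol`) have no defined mean and are flagged.
#'
#' @param field a \code{WaveField}.
#' @param minSamples minimum number of valid samples per node (default 2).
#' @param tol resultant length below which the mean is undefined.
#' @return data.frame with node, meanDir (rad), circSD (rad), resultant,
#'   nValid, defined.
#' @export
meanDirectionMap <- function(field, minSamples = 2L, tol = 1e-8) {
  ang <- atan2(field@dirY, field@dirX)
  n <- ncol(ang)
  res <- data.frame(node = seq_len(n), meanDir = NA_real_,
                    circSD = NA_real_, resultant = NA_real_,
                    nValid = 0L, defined = FALSE)
  for (j in seq_len(n)) {
    a <- ang[, j]; a <- a[is.finite(a)]
    res$nValid[j] <- length(a)
    if (length(a) < minSamples) next
    z <- mean(exp(1i * a))
    res$resultant[j] <- Mod(z)
    if (Mod(z) < tol) next
    res$meanDir[j] <- Arg(z)
    res$circSD[j] <- sqrt(-2 * log(Mod(z)))
    res$defined[j] <- TRUE
  }
  res
}

#' Source-sink index at a radius around a node
#'
#' Mean over annulus members of \eqn{(x_k - x_j) \cdot g_k}, where the
#' field g is by default the outward-positive propagation-direction field
#' (-grad theta' for advancing phase), so a locally generated outward
#' radial wave (phase cone) around a source gives a positive value and a
#' sink a negative one. With `useRawGradient = TRUE` the raw fitted
#' gradient enters instead (sign flipped).
#'
#' @param map a \code{SurfaceMap}.
#' @param gradients nodes x 2 matrix of fitted phase gradients for one
#'   snapshot, rad/mm (columns gx, gy).
#' @param center node index at the annulus centre.
#' @param r annulus radius, mm.
#' @param dr annulus half-width, mm (default 10).
#' @param minNodes minimum annulus members with valid gradients (default 5).
#' @param useRawGradient use +grad instead of -grad as the field.
#' @return SSI value (rad), or NA when the annulus holds too few valid
#'   gradients.
#' @export
ssi <- function(map, gradients, center, r, dr = 10, minNodes = 5L,
                useRawGradient = FALSE) {
  x <- mapCoords(map)
  dx <- sweep(x, 2, x[center, ])
  dist <- sqrt(rowSums(dx^2))
  g <- if (useRawGradient) gradients else -gradients
  inAnn <- dist > (r - dr) & dist < (r + dr)
  ok <- inAnn & is.finite(g[, 1]) & is.finite(g[, 2])
  ok[center] <- FALSE
  if (sum(ok) < minNodes) return(NA_real_)
  mean(rowSums(dx[ok, , drop = FALSE] * g[ok, , drop = FALSE]))
}

#' Source-sink index series over a trajectory's samples
#'
#' @param map a \code{SurfaceMap}.
#' @param field a \code{WaveField}.
#' @inheritParams ssi
#' @return numeric vector, one SSI per sample (NA where undefined).
#' @export
ssiSeries <- function(map, field, center, r, dr = 10, minNodes = 5L,
                      useRawGradient = FALSE) {
  S <- nrow(field@gx)
  vapply(seq_len(S), function(s) {
    ssi(map, cbind(field@gx[s, ], field@gy[s, ]), center, r, dr = dr,
        minNodes = minNodes, useRawGradient = useRawGradient)
  }, numeric(1))
}
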