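#' Configuration for the delay-coupled phase-oscillator simulation
#'
#' The network integrates
#' \deqn{d\theta_j/dt = \omega_j(t) + \lambda \sum_k w_{jk}
#'   \sin(\theta_k(t - \tau_{jk}) - \theta_j(t))}
#' by forward Euler with a ring-buffer delay history. Intrinsic frequencies
#' \eqn{f_j = \omega_j / 2\pi} are redrawn i.i.d. from Gaussian(f0, sigmaF)
#' at the start of every epoch. One analysis snapshot is retained per epoch
#' (at `sampleOffset` after the redraw) once the discard window has passed.
#'
#' @param f0 mean intrinsic frequency, Hz (default 10).
#' @param sigmaF standard deviation of intrinsic frequency, Hz (default
#'   0.5, i.e. sigmaF/f0 = 0.05).
#' @param coupling global coupling strength lambda, rad/s per unit total
#'   input weight (default 10; with generator weights normalised to unit
#'   mean row sum this is the effective per-node coupling rate, placing the
#'   network in the partially synchronised traveling-wave regime).
#' @param dt integration step, s (default 1e-3; must be smaller than the
#'   smallest positive delay).
#' @param tTotal total simulated time, s (default 101).
#' @param epochLen length of one intrinsic-frequency epoch, s (default 0.5).
#' @param sampleOffset snapshot time within each epoch, s (default 0.3).
#' @param discard initial transient discarded from analysis, s (default 1).
#' @param seed integer RNG seed for the frequency schedule and initial
#'   phases.
#' @return a \code{SimulationConfig} object.
#' @export
simulationConfig <- function(f0 = 10, sigmaF = 0.5, coupling = 10,
                             dt = 1e-3, tTotal = 101, epochLen = 0.5,
                             sampleOffset = 0.3, discard = 1, seed = 1L) {
  cfg <- list(f0 = f0, sigmaF = sigmaF, coupling = coupling, dt = dt,
              tTotal = tTotal, epochLen = epochLen,
              sampleOffset = sampleOffset, discard = discard,
              seed = as.integer(seed))
  if (dt <= 0) stop("invalid config: dt must be > 0")
  if (sigmaF < 0) stop("invalid config: sigmaF must be >= 0")
  if (cfg$sampleOffset >= cfg$epochLen) {
    stop("invalid config: sampleOffset must be < epochLen")
  }
  if (cfg$tTotal < cfg$discard + cfg$epochLen) {
    stop("invalid config: tTotal must be >= discard + epochLen")
  }
  structure(cfg, class = "SimulationConfig")
}

#' Low-level delay-coupled Kuramoto integrator
#'
#' Forward-Euler integration with explicit control over the per-epoch
#' intrinsic-frequency matrix and initial phases. [simulateNetwork()] is the
#' seeded front end; this entry point is useful for controlled experiments
#' (fixed frequency assignments, two-oscillator closed forms).
#'
#' Delays are rounded to the nearest integer multiple of `dt`
#' (pairs with zero weight are skipped). History before t = 0 extrapolates
#' each node backward at its initial intrinsic rate.
#'
#' @param weights N x N symmetric nonnegative coupling matrix.
#' @param delayMatrix N x N delays, seconds.
#' @param freqMatrix nEpochs x N intrinsic frequencies, Hz (one row per
#'   epoch of length `epochLen`).
#' @param theta0 initial phases, radians.
#' @param coupling global coupling lambda.
#' @param dt integration step, s.
#' @param epochLen epoch length, s.
#' @param sampleOffset snapshot offset within each epoch, s; snapshots are
#'   taken at `epochStart + sampleOffset` for every epoch at or after
#'   `discard`.
#' @param discard initial time window excluded from sampling, s.
#' @return list with `sampleTimes`, `phases` (samples x N, wrapped to
#'   (-pi, pi]), `instRates` (samples x N, rad/s) and `epochFreqs`
#'   (samples x N, Hz).
#' @export
kuramotoIntegrate <- function(weights, delayMatrix, freqMatrix, theta0,
                              coupling, dt = 1e-3, epochLen = 0.5,
                              sampleOffset = 0.3, discard = 0) {
  n <- ncol(freqMatrix)
  stopifnot(nrow(weights) == n, ncol(weights) == n,
            all(dim(delayMatrix) == c(n, n)), length(theta0) == n)
  posDelay <- delayMatrix[weights > 0 & delayMatrix > 0]
  if (length(posDelay) && dt >= min(posDelay)) {
    stop(sprintf("config error: dt = %g s is not below the smallest positive delay (%g s)",
                 dt, min(posDelay)))
  }
  stepsPerEpoch <- round(epochLen / dt)
  if (abs(stepsPerEpoch * dt - epochLen) > 1e-9) {
    stop("config error: epochLen must be an integer multiple of dt")
  }
  delaySteps <- matrix(as.integer(round(delayMatrix / dt)), n, n)
  nEpochs <- nrow(freqMatrix)
  epochStarts <- (seq_len(nEpochs) - 1L) * epochLen
  keep <- which(epochStarts >= discard - 1e-12)
  if (!length(keep)) stop("config error: no epochs remain after the discard window")
  offSteps <- round(sampleOffset / dt)
  sampleSteps <- as.integer((keep - 1L) * stepsPerEpoch + offSteps)
  out <- kuramotoEulerCpp(weights, delaySteps, 2 * pi * freqMatrix,
                          as.numeric(theta0), dt, as.integer(stepsPerEpoch),
                          coupling, sampleSteps, as.integer(keep - 1L))
  list(sampleTimes = epochStarts[keep] + offSteps * dt,
       phases = out$phases,
       instRates = out$instRates,
       epochFreqs = freqMatrix[keep, , drop = FALSE])
}

#' Simulate a connectome network of delay-coupled phase oscillators
#'
#' Draws the per-epoch intrinsic-frequency schedule (i.i.d. Gaussian(f0,
#' sigmaF) per node per epoch) and uniform initial phases under the config
#' seed, integrates the delay-coupled network, and returns one retained
#' snapshot per post-discard epoch together with relative phases.
#'
#' @param net a \code{ConnectomeNetwork}.
#' @param cfg a \code{SimulationConfig} from [simulationConfig()].
#' @return a \code{PhaseTrajectory}.
#' @examples
#' net <- generateConnectome(syntheticConfig(nNodes = 40, seed = 1))
#' traj <- simulateNetwork(net, simulationConfig(tTotal = 3, seed = 1))
#' traj
#' @export
simulateNetwork <- function(net, cfg = simulationConfig()) {
  stopifnot(is(net, "ConnectomeNetwork"))
  if (!inherits(cfg, "SimulationConfig")) stop("cfg must be a SimulationConfig")
  n <- nNodes(net)
  nEpochs <- floor(cfg$tTotal / cfg$epochLen)
  seeds <- subSeeds(cfg$seed, c("schedule", "theta0"))
  set.seed(seeds[["schedule"]])
  freqMatrix <- matrix(stats::rnorm(nEpochs * n, cfg$f0, cfg$sigmaF),
                       nEpochs, n)
  set.seed(seeds[["theta0"]])
  theta0 <- stats::runif(n, -pi, pi)
  res <- kuramotoIntegrate(edgeWeights(net), delays(net), freqMatrix,
                           theta0, coupling = cfg$coupling, dt = cfg$dt,
                           epochLen = cfg$epochLen,
                           sampleOffset = cfg$sampleOffset,
                           discard = cfg$discard)
  rel <- t(apply(res$phases, 1, relativePhase))
  new("PhaseTrajectory", sampleTimes = res$sampleTimes,
      phases = res$phases, relPhases = rel,
      epochFreqs = res$epochFreqs, instRates = res$instRates,
      config = unclass(cfg))
}

#' Relative phase of a snapshot
#'
#' Subtracts the argument of the network mean phasor from every phase and
#' wraps to (-pi, pi], so the snapshot's mean phasor has argument zero.
#' Stabilises the spatial phase pattern against global rotation.
#'
#' @param phasesSnapshot numeric vector of phases, radians.
#' @return numeric vector of relative phases in (-pi, pi].
#' @export
relativePhase <- function(phasesSnapshot) {
  if (!length(phasesSnapshot)) stop("need at least one phase")
  wrapAngle(phasesSnapshot - circularMean(phasesSnapshot))
}

#' Kuramoto order parameter
#'
#' Modulus of the mean unit phasor: 1 for full synchrony, 0 for perfectly
#' balanced phases.
#'
#' @param phasesSnapshot numeric vector (one snapshot) or samples x nodes
#'   matrix of phases, radians.
#' @return scalar in [0, 1], or one value per row for a matrix.
#' @export
orderParameter <- function(phasesSnapshot) {
  if (is.matrix(phasesSnapshot)) {
    Mod(rowMeans(exp(1i * phasesSnapshot)))
  } else {
    Mod(mean(exp(1i * phasesSnapshot)))
  }
}

#' Write a phase trajectory to delimited text files
#'
#' `samples.tsv` has one row per sample and node (time, node, phase,
#' rel_phase, inst_rate); `epoch_freqs.tsv` one row per sample and node
#' (time, node, freq); `config.json` echoes the simulation configuration.
#'
#' @param traj a \code{PhaseTrajectory}.
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
writeTrajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- length(sampleTimes(traj)); n <- ncol(phases(traj))
  tab <- data.frame(time = rep(sampleTimes(traj), n),
                    node = rep(seq_len(n) - 1L, each = s),
                    phase = as.vector(phases(traj)),
                    rel_phase = as.vector(relPhases(traj)),
                    inst_rate = as.vector(instRates(traj)))
  utils::write.table(tab, file.path(dir, "samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ef <- data.frame(time = rep(sampleTimes(traj), n),
                   node = rep(seq_len(n) - 1L, each = s),
                   freq = as.vector(epochFreqs(traj)))
  utils::write.table(ef, file.path(dir, "epoch_freqs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(traj@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
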