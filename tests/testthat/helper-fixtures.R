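# Shared fixtures. Expensive simulations are computed once per test run and
# memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Scaled-down study-condition run: 150 nodes, 21 s (40 retained epochs),
# f0 = 10 Hz, sigma_f/f0 = 0.05, default coupling.
ciRun <- function() {
  fixture("ciRun", function() {
    net <- generateConnectome(syntheticConfig(nNodes = 150, seed = 101))
    traj <- simulateNetwork(net, simulationConfig(tTotal = 21, seed = 202))
    map <- projectSurface(net)
    field <- waveField(map, traj)
    list(net = net, traj = traj, map = map, field = field)
  })
}

# Same network, homogeneous intrinsic frequencies (sigma_f = 0).
ciRunHomogeneous <- function() {
  fixture("ciRunHomogeneous", function() {
    net <- ciRun()$net
    traj <- simulateNetwork(net, simulationConfig(tTotal = 21, sigmaF = 0,
                                                  seed = 202))
    list(net = net, traj = traj)
  })
}

# A minimal valid ConnectomeNetwork around hand-placed coordinates, for
# geometry tests (no dynamics: zero weights and lengths).
geometryNet <- function(coords, hemisphere = rep("L", nrow(coords))) {
  n <- nrow(coords)
  z <- matrix(0, n, n)
  new("ConnectomeNetwork", coords = coords, hemisphere = hemisphere,
      weights = z, tractLengths = z, delays = z, velocity = 10.8,
      volumes = rep(1, n), networkLabels = rep(1L, n),
      degrees = rep(0, n))
}

# Random planar node layout (jittered grid, so annuli are nearly
# symmetric), as a single-hemisphere SurfaceMap.
gridMap <- function(nx = 24, ny = 24, spacing = 8, jitter = 1.5,
                    seed = 42) {
  set.seed(seed)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  xy <- cbind(g$x * spacing + rnorm(nrow(g), 0, jitter),
              g$y * spacing + rnorm(nrow(g), 0, jitter))
  surfaceMap(xy)
}

# PhaseTrajectory built from raw phase snapshots (samples x nodes), with
# given per-epoch frequencies; used to probe metrics in isolation.
syntheticTrajectory <- function(phaseMatrix, freqMatrix,
                                rates = NULL, times = NULL) {
  S <- nrow(phaseMatrix)
  ph <- wrapAngle(phaseMatrix)
  rel <- t(apply(ph, 1, relativePhase))
  if (is.null(rates)) rates <- matrix(2 * pi * 10, S, ncol(ph))
  if (is.null(times)) times <- seq_len(S)
  new("PhaseTrajectory", sampleTimes = as.numeric(times), phases = ph,
      relPhases = rel, epochFreqs = freqMatrix, instRates = rates,
      config = list(f0 = 10))
}

# WaveField built directly from gradient matrices (dirs from -grad).
syntheticField <- function(gx, gy, rates = NULL) {
  if (is.null(rates)) rates <- matrix(2 * pi * 10, nrow(gx), ncol(gx))
  gn <- sqrt(gx^2 + gy^2)
  ok <- is.finite(gn) & gn > 0
  sgn <- sign(rates)
  new("WaveField", gx = gx, gy = gy,
      speeds = ifelse(ok, abs(rates) / gn / 1000, NA_real_),
      dirX = ifelse(ok, -gx / gn * sgn, NA_real_),
      dirY = ifelse(ok, -gy / gn * sgn, NA_real_),
      windowSigma = 20)
}
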