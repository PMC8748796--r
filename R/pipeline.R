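# Orchestration: full experiment (generate -> simulate -> map -> analyze ->
# report) and the coupling / frequency-spread / mean-frequency sweeps.

.ciDefaults <- list(connectome = list(nNodes = 150L),
                    simulation = list(tTotal = 21))
.fullDefaults <- list(connectome = list(nNodes = 468L),
                      simulation = list(tTotal = 101))

#' Build an experiment configuration
#'
#' @param profile "ci" (150 nodes, 21 s, 40 retained epochs) or "full"
#'   (468 nodes, 101 s, 200 retained epochs).
#' @param connectome named list of [syntheticConfig()] overrides.
#' @param simulation named list of [simulationConfig()] overrides.
#' @param analysis named list: windowSigma (mm), nPerm, ssiRadii (mm),
#'   groupingAreas (cm^2).
#' @param seed root seed; all stage seeds are derived from it.
#' @return a named list suitable for [runExperiment()].
#' @export
experimentConfig <- function(profile = c("ci", "full"), connectome = list(),
                             simulation = list(), analysis = list(),
                             seed = 1L) {
  profile <- match.arg(profile)
  base <- if (profile == "ci") .ciDefaults else .fullDefaults
  ana <- utils::modifyList(list(windowSigma = 20, nPerm = 2000,
                                ssiRadii = c(20, 30, 40, 50, 70, 90),
                                groupingAreas = exp(seq(log(10), log(400),
                                                        length.out = 12))),
                           analysis)
  list(profile = profile, seed = as.integer(seed),
       connectome = utils::modifyList(base$connectome, connectome),
       simulation = utils::modifyList(base$simulation, simulation),
       analysis = ana)
}

.loadConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (key in c("seed", "connectome", "simulation")) {
    if (is.null(config[[key]])) {
      stop(sprintf("config error: missing required key '%s'", key))
    }
  }
  if (is.null(config$analysis)) config$analysis <- list()
  if (is.null(config$profile)) config$profile <- "ci"
  config
}

#' Run the full traveling-wave experiment
#'
#' Generates (or loads) the connectome, simulates the delay-coupled
#' network, projects nodes to the equal-area map, estimates the wave
#' field, and computes the headline metrics: order parameter, propagation
#' speeds, relative-phase PCA, network segmentation, sequencing effect and
#' the degree-phase correlation. Deterministic given the root seed.
#'
#' @param config a list from [experimentConfig()], or a path to a YAML/JSON
#'   file with keys seed, connectome, simulation (optional analysis,
#'   profile).
#' @param outDir optional directory: tables, summary JSON and a run
#'   manifest are written there.
#' @param net optional pre-built \code{ConnectomeNetwork} (skips
#'   generation; used when analysing a user-supplied connectome).
#' @return list with `net`, `traj`, `map`, `field`, `segmentation`,
#'   `sequencing`, `pca`, `degreeCor` and `summary` (named numeric vector).
#' @export
runExperiment <- function(config = experimentConfig(), outDir = NULL,
                          net = NULL) {
  config <- .loadConfig(config)
  seeds <- subSeeds(config$seed, c("connectome", "simulation", "perm"))
  if (is.null(net)) {
    ccfg <- do.call(syntheticConfig,
                    utils::modifyList(config$connectome,
                                      list(seed = seeds[["connectome"]])))
    net <- generateConnectome(ccfg)
  }
  scfg <- do.call(simulationConfig,
                  utils::modifyList(config$simulation,
                                    list(seed = seeds[["simulation"]])))
  traj <- simulateNetwork(net, scfg)
  map <- projectSurface(net)
  field <- waveField(map, traj, windowSigma = config$analysis$windowSigma)
  seg <- segmentation(traj, networkLabels(net),
                      nPerm = config$analysis$nPerm, seed = seeds[["perm"]])
  seqEff <- sequencingEffect(traj, net)
  pca <- relativePhasePCA(traj)
  degCor <- networkPhaseDegreeCor(traj, net)
  R <- orderParameter(phases(traj))
  sp <- field@speeds[is.finite(field@speeds)]
  summary <- c(uci_slope_mean = seqEff$meanSlope,
               uci_slope_t = seqEff$tValue,
               segmentation_d_mean = seg$meanD,
               segmentation_f_mean = seg$meanF,
               speed_median = stats::median(sp),
               speed_iqr_lo = unname(stats::quantile(sp, 0.25)),
               speed_iqr_hi = unname(stats::quantile(sp, 0.75)),
               R_mean = mean(R),
               pc1_explained = pca$explained[1],
               degree_phase_r = degCor$r)
  out <- list(net = net, traj = traj, map = map, field = field,
              segmentation = seg, sequencing = seqEff, pca = pca,
              degreeCor = degCor, summary = summary, config = config)
  if (!is.null(outDir)) .writeExperiment(out, outDir)
  out
}

.writeExperiment <- function(out, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  net <- out$net; map <- out$map; field <- out$field; traj <- out$traj
  writeConnectome(net, file.path(outDir, "connectome"))
  writeTrajectory(traj, file.path(outDir, "trajectory"))
  nodes <- data.frame(node_id = seq_len(nNodes(net)) - 1L,
                      map_x = mapCoords(map)[, 1],
                      map_y = mapCoords(map)[, 2],
                      degree = nodeDegrees(net),
                      label = networkLabels(net))
  utils::write.table(nodes, file.path(outDir, "map_nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  S <- nrow(field@gx); n <- ncol(field@gx)
  wf <- data.frame(time = rep(sampleTimes(traj), n),
                   node = rep(seq_len(n) - 1L, each = S),
                   gx = as.vector(field@gx), gy = as.vector(field@gy),
                   speed = as.vector(field@speeds),
                   dir = as.vector(atan2(field@dirY, field@dirX)))
  utils::write.table(wf, file.path(outDir, "wave_field.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(out$segmentation$pairTable,
                     file.path(outDir, "segmentation_pairs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(out$summary), file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(out$config, cfgPath, auto_unbox = TRUE, digits = NA)
  manifest <- list(config_md5 = unname(tools::md5sum(cfgPath)),
                   seed = out$config$seed,
                   package_version = as.character(utils::packageVersion("cortexwaves")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Specification of a parameter sweep
#'
#' @param couplingValues global coupling strengths to scan.
#' @param sigmaRatioValues values of sigma_f / f0 to scan (canonical grid:
#'   0.025, 0.05, 0.1; default is the single study value 0.05).
#' @param f0Values mean intrinsic frequencies, Hz (canonical band grid: 5,
#'   10, 20, 40 for theta, alpha, beta, gamma; default 10).
#' @param replicates simulated replicates per grid point.
#' @param seed root seed.
#' @return a \code{SweepSpec} list.
#' @export
sweepSpec <- function(couplingValues = 10, sigmaRatioValues = 0.05,
                      f0Values = 10, replicates = 1L, seed = 1L) {
  if (any(couplingValues <= 0) || any(sigmaRatioValues < 0) ||
      any(f0Values <= 0)) {
    stop("sweep values must be positive (sigma ratios nonnegative)")
  }
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(couplingValues = couplingValues,
                 sigmaRatioValues = sigmaRatioValues, f0Values = f0Values,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)), class = "SweepSpec")
}

#' Run a parameter sweep
#'
#' Full factorial over coupling, sigma_f/f0 and f0. Each grid point runs
#' the scaled-down experiment and reports the four panel statistics:
#' median propagation speed, mean pairwise segmentation d, mean UCI slope
#' and mean order parameter. Per-point failures are recorded (NA row with
#' the error message) and the sweep continues.
#'
#' @param sweep a \code{SweepSpec}.
#' @param profile experiment scale, "ci" or "full".
#' @param nPerm label permutations inside each point's segmentation
#'   analysis (0 skips permutation inference, which sweeps do not need).
#' @param connectome,simulation named lists of extra [syntheticConfig()] /
#'   [simulationConfig()] overrides applied to every grid point.
#' @return data.frame, one row per grid point and replicate.
#' @export
runSweep <- function(sweep = sweepSpec(), profile = "ci", nPerm = 0,
                     connectome = list(), simulation = list()) {
  grid <- expand.grid(coupling = sweep$couplingValues,
                      sigmaRatio = sweep$sigmaRatioValues,
                      f0 = sweep$f0Values, replicate = seq_len(sweep$replicates))
  seeds <- subSeeds(sweep$seed, paste0("pt", seq_len(nrow(grid))))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    base <- data.frame(coupling = g$coupling, sigmaRatio = g$sigmaRatio,
                       f0 = g$f0, replicate = g$replicate)
    res <- tryCatch({
      cfg <- experimentConfig(profile = profile,
                              connectome = connectome,
                              simulation = utils::modifyList(
                                simulation,
                                list(f0 = g$f0, sigmaF = g$sigmaRatio * g$f0,
                                     coupling = g$coupling)),
                              analysis = list(nPerm = nPerm),
                              seed = seeds[[i]])
      s <- runExperiment(cfg)$summary
      cbind(base, speed_median = s[["speed_median"]],
            segmentation_d_mean = s[["segmentation_d_mean"]],
            uci_slope_mean = s[["uci_slope_mean"]],
            R_mean = s[["R_mean"]], error = NA_character_)
    }, error = function(e) {
      cbind(base, speed_median = NA_real_, segmentation_d_mean = NA_real_,
            uci_slope_mean = NA_real_, R_mean = NA_real_,
            error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}
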