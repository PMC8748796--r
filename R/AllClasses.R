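#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ConnectomeNetwork: a spatially embedded cortical network
#'
#' Container for a parcellated connectome: node positions in 3-D (mm),
#' hemisphere membership, symmetric connection weights, tract lengths (mm),
#' conduction delays (s, always `tractLengths / velocity`), node volumes
#' (mm^3), a 7-way resting-state-network style parcel labelling, and
#' weighted node degrees normalised to [0, 1].
#'
#' @slot coords numeric matrix, nodes x 3, positions in mm.
#' @slot hemisphere character vector, one of "L"/"R" per node.
#' @slot weights symmetric nonnegative numeric matrix with zero diagonal.
#' @slot tractLengths symmetric nonnegative matrix, mm, zero diagonal;
#'   entries never shorter than the straight-line distance.
#' @slot delays conduction delay matrix, seconds; `tractLengths / velocity`.
#' @slot velocity conduction velocity, m/s.
#' @slot volumes node volumes, mm^3.
#' @slot networkLabels integer vector in `1..max(networkLabels)` assigning
#'   each node to a spatially contiguous network parcel.
#' @slot degrees weighted node degree (row sum of weights), rescaled to [0,1].
#'
#' @export
setClass("ConnectomeNetwork",
  representation(
    coords = "matrix",
    hemisphere = "character",
    weights = "matrix",
    tractLengths = "matrix",
    delays = "matrix",
    velocity = "numeric",
    volumes = "numeric",
    networkLabels = "integer",
    degrees = "numeric"
  )
)

setValidity("ConnectomeNetwork", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be an n x 3 matrix")
  for (nm in c("weights", "tractLengths", "delays")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n))) msg <- c(msg, sprintf("%s must be %d x %d", nm, n, n))
  }
  if (length(object@hemisphere) != n ||
      !all(object@hemisphere %in% c("L", "R"))) {
    msg <- c(msg, "hemisphere must be 'L'/'R' for every node")
  }
  if (length(msg)) return(msg)
  w <- object@weights; L <- object@tractLengths; D <- object@delays
  if (any(w < 0) || any(L < 0)) msg <- c(msg, "weights and tractLengths must be nonnegative")
  if (max(abs(w - t(w))) > 1e-8 * max(1, max(abs(w)))) msg <- c(msg, "weights must be symmetric")
  if (max(abs(L - t(L))) > 1e-8 * max(1, max(abs(L)))) msg <- c(msg, "tractLengths must be symmetric")
  if (any(diag(w) != 0) || any(diag(L) != 0)) msg <- c(msg, "weights/tractLengths need zero diagonal")
  if (length(object@velocity) != 1L || object@velocity <= 0) msg <- c(msg, "velocity must be a positive scalar")
  # delays are definitionally L / v, with v in m/s and L in mm
  if (max(abs(D - L / (object@velocity * 1000))) > 1e-10) {
    msg <- c(msg, "delays must equal tractLengths / velocity")
  }
  d3 <- as.matrix(stats::dist(object@coords))
  nz <- L > 0
  if (any(L[nz] < d3[nz] - 1e-6)) {
    msg <- c(msg, "tractLengths must be >= Euclidean distance where nonzero")
  }
  if (length(object@volumes) != n || any(object@volumes <= 0)) msg <- c(msg, "volumes must be positive, one per node")
  if (length(object@networkLabels) != n || any(object@networkLabels < 1L)) {
    msg <- c(msg, "networkLabels must be positive integers, one per node")
  }
  if (length(object@degrees) != n || any(object@degrees < 0) || any(object@degrees > 1)) {
    msg <- c(msg, "degrees must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' SurfaceMap: 2-D equal-area projection of the connectome nodes
#'
#' Per-hemisphere Lambert azimuthal equal-area projection of node positions,
#' used by all spatial wave analyses. The two hemispheres occupy disjoint
#' half-planes.
#'
#' @slot coords2d numeric matrix, nodes x 2, map positions in mm.
#' @slot hemisphere character vector "L"/"R" per node.
#' @slot hemisphereCenters 2 x 2 matrix (rows L, R) of map centres, mm.
#' @slot meta list with projection poles, sphere radii and 3-D centroids.
#' @export
setClass("SurfaceMap",
  representation(
    coords2d = "matrix",
    hemisphere = "character",
    hemisphereCenters = "matrix",
    meta = "list"
  )
)

setValidity("SurfaceMap", function(object) {
  msg <- character()
  if (ncol(object@coords2d) != 2L) msg <- c(msg, "coords2d must be n x 2")
  if (nrow(object@coords2d) != length(object@hemisphere)) {
    msg <- c(msg, "hemisphere length must match coords2d rows")
  }
  if (length(msg)) msg else TRUE
})

#' PhaseTrajectory: sampled phase snapshots of a network simulation
#'
#' One row per retained analysis sample (one per intrinsic-frequency epoch
#' after the discard window), one column per node. Phases are wrapped to
#' (-pi, pi]; relative phases subtract the argument of the network mean
#' phasor; `instRates` holds the model right-hand side d(theta)/dt (rad/s)
#' at the snapshot; `epochFreqs` the intrinsic frequencies (Hz) in force.
#'
#' @slot sampleTimes numeric vector of snapshot times, s.
#' @slot phases samples x nodes matrix of phases, (-pi, pi].
#' @slot relPhases samples x nodes matrix of relative phases, (-pi, pi].
#' @slot epochFreqs samples x nodes matrix of intrinsic frequencies, Hz.
#' @slot instRates samples x nodes matrix of instantaneous rates, rad/s.
#' @slot config list echoing the simulation configuration.
#' @export
setClass("PhaseTrajectory",
  representation(
    sampleTimes = "numeric",
    phases = "matrix",
    relPhases = "matrix",
    epochFreqs = "matrix",
    instRates = "matrix",
    config = "list"
  )
)

setValidity("PhaseTrajectory", function(object) {
  d <- dim(object@phases)
  msg <- character()
  for (nm in c("relPhases", "epochFreqs", "instRates")) {
    if (!all(dim(slot(object, nm)) == d)) msg <- c(msg, sprintf("%s must match phases dims", nm))
  }
  if (length(object@sampleTimes) != d[1]) msg <- c(msg, "sampleTimes must have one entry per sample")
  if (length(msg)) return(msg)
  if (any(object@phases > pi | object@phases <= -pi)) msg <- c(msg, "phases must lie in (-pi, pi]")
  # each row of relPhases has mean phasor with argument 0 by construction
  args <- abs(Arg(rowMeans(exp(1i * object@relPhases))))
  if (any(args > 1e-9)) msg <- c(msg, "relPhases rows must have circular-mean argument 0")
  if (length(msg)) msg else TRUE
})
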