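# Accessor generics for the S4 containers. Slots are never touched directly
# by user code; these are the supported surface.

#' @rdname ConnectomeNetwork-class
#' @param object,x a \code{ConnectomeNetwork}, \code{SurfaceMap} or
#'   \code{PhaseTrajectory}.
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("hemispheres", function(object) standardGeneric("hemispheres"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("tractLengths", function(object) standardGeneric("tractLengths"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("delays", function(object) standardGeneric("delays"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("nodeVolumes", function(object) standardGeneric("nodeVolumes"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("networkLabels", function(object) standardGeneric("networkLabels"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("nodeDegrees", function(object) standardGeneric("nodeDegrees"))

#' @rdname ConnectomeNetwork-class
#' @export
setGeneric("conductionVelocity", function(object) standardGeneric("conductionVelocity"))

#' @rdname SurfaceMap-class
#' @export
setGeneric("mapCoords", function(object) standardGeneric("mapCoords"))

#' @rdname PhaseTrajectory-class
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname PhaseTrajectory-class
#' @export
setGeneric("phases", function(object) standardGeneric("phases"))

#' @rdname PhaseTrajectory-class
#' @export
setGeneric("relPhases", function(object) standardGeneric("relPhases"))

#' @rdname PhaseTrajectory-class
#' @export
setGeneric("epochFreqs", function(object) standardGeneric("epochFreqs"))

#' @rdname PhaseTrajectory-class
#' @export
setGeneric("instRates", function(object) standardGeneric("instRates"))

setMethod("nNodes", "ConnectomeNetwork", function(object) nrow(object@coords))
setMethod("nodeCoords", "ConnectomeNetwork", function(object) object@coords)
setMethod("hemispheres", "ConnectomeNetwork", function(object) object@hemisphere)
setMethod("edgeWeights", "ConnectomeNetwork", function(object) object@weights)
setMethod("tractLengths", "ConnectomeNetwork", function(object) object@tractLengths)
setMethod("delays", "ConnectomeNetwork", function(object) object@delays)
setMethod("nodeVolumes", "ConnectomeNetwork", function(object) object@volumes)
setMethod("networkLabels", "ConnectomeNetwork", function(object) object@networkLabels)
setMethod("nodeDegrees", "ConnectomeNetwork", function(object) object@degrees)
setMethod("conductionVelocity", "ConnectomeNetwork", function(object) object@velocity)

setMethod("nNodes", "SurfaceMap", function(object) nrow(object@coords2d))
setMethod("mapCoords", "SurfaceMap", function(object) object@coords2d)
setMethod("hemispheres", "SurfaceMap", function(object) object@hemisphere)

setMethod("sampleTimes", "PhaseTrajectory", function(object) object@sampleTimes)
setMethod("phases", "PhaseTrajectory", function(object) object@phases)
setMethod("relPhases", "PhaseTrajectory", function(object) object@relPhases)
setMethod("epochFreqs", "PhaseTrajectory", function(object) object@epochFreqs)
setMethod("instRates", "PhaseTrajectory", function(object) object@instRates)

setMethod("show", "ConnectomeNetwork", function(object) {
  n <- nNodes(object)
  nz <- sum(object@weights > 0) / 2
  cat("ConnectomeNetwork with", n, "nodes\n")
  cat("  hemispheres: L =", sum(object@hemisphere == "L"),
      " R =", sum(object@hemisphere == "R"), "\n")
  cat("  connections:", nz, sprintf("(density %.2f)", nz / (n * (n - 1) / 2)), "\n")
  cat(sprintf("  tract length: mean %.1f mm; delay: mean %.2f ms (v = %.1f m/s)\n",
              mean(object@tractLengths[object@weights > 0]),
              1000 * mean(object@delays[object@weights > 0]),
              object@velocity))
  cat("  network parcels:", length(unique(object@networkLabels)), "\n")
})

setMethod("show", "SurfaceMap", function(object) {
  cat("SurfaceMap with", nNodes(object), "nodes (Lambert azimuthal equal-area)\n")
  rng <- apply(object@coords2d, 2, range)
  cat(sprintf("  extent: x [%.0f, %.0f] mm, y [%.0f, %.0f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
})

setMethod("show", "PhaseTrajectory", function(object) {
  cat("PhaseTrajectory:", nrow(object@phases), "samples x",
      ncol(object@phases), "nodes\n")
  cat(sprintf("  time range [%.2f, %.2f] s\n",
              min(object@sampleTimes), max(object@sampleTimes)))
  R <- Mod(rowMeans(exp(1i * object@phases)))
  cat(sprintf("  order parameter R: mean %.3f (range %.3f-%.3f)\n",
              mean(R), min(R), max(R)))
})
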