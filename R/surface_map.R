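#' Construct a SurfaceMap from raw 2-D coordinates
#'
#' Low-level constructor used by analyses that already have planar node
#' positions (planted wave fields, ring layouts). [projectSurface()] is the
#' standard route from a \code{ConnectomeNetwork}.
#'
#' @param coords2d numeric n x 2 matrix of map positions, mm.
#' @param hemisphere character vector of "L"/"R" per node; defaults to a
#'   single hemisphere "L".
#' @return a \code{SurfaceMap}.
#' @export
surfaceMap <- function(coords2d, hemisphere = rep("L", nrow(coords2d))) {
  coords2d <- as.matrix(coords2d)
  centers <- rbind(L = colMeans(coords2d[hemisphere == "L", , drop = FALSE]),
                   R = if (any(hemisphere == "R"))
                     colMeans(coords2d[hemisphere == "R", , drop = FALSE])
                   else c(NA_real_, NA_real_))
  new("SurfaceMap", coords2d = coords2d, hemisphere = hemisphere,
      hemisphereCenters = centers, meta = list(projection = "direct"))
}

# Orthonormal tangent basis perpendicular to a unit pole vector.
.tangentBasis <- function(pole) {
  ref <- if (abs(pole[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * pole) * pole
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(pole[2] * e1[3] - pole[3] * e1[2],
          pole[3] * e1[1] - pole[1] * e1[3],
          pole[1] * e1[2] - pole[2] * e1[1])
  rbind(e1, e2)
}

#' Project a connectome onto a 2-D equal-area cortical map
#'
#' Per hemisphere, node positions are radially normalised to the unit
#' sphere around the hemisphere centroid and mapped by Lambert's azimuthal
#' equal-area projection about the given pole (planar radius
#' \eqn{2\sin(\psi/2)} at angular distance \eqn{\psi} from the pole), then
#' rescaled to mm by the hemisphere's mean sphere radius. The two
#' hemispheres are placed on disjoint half-planes (left at negative map x,
#' right at positive).
#'
#' Nodes at (or numerically near) the antipode of the pole have no defined
#' azimuth; they are placed on the map boundary at planar radius 2 with a
#' warning.
#'
#' @param net a \code{ConnectomeNetwork}.
#' @param poleL,poleR unit 3-vectors: projection poles for the left/right
#'   hemisphere. Defaults approximate lateral scalp directions (10-20 C3/C4
#'   like), i.e. the outward x axis tilted toward the vertex.
#' @return a \code{SurfaceMap}.
#' @export
projectSurface <- function(net,
                           poleL = c(-sin(pi / 3), 0, cos(pi / 3)),
                           poleR = c(+sin(pi / 3), 0, cos(pi / 3))) {
  stopifnot(is(net, "ConnectomeNetwork"))
  poleL <- poleL / sqrt(sum(poleL^2))
  poleR <- poleR / sqrt(sum(poleR^2))
  hemi <- hemispheres(net)
  coords <- nodeCoords(net)
  out <- matrix(NA_real_, nNodes(net), 2)
  meta <- list(projection = "lambert-azimuthal-equal-area",
               poles = list(L = poleL, R = poleR), radii = c(L = NA, R = NA),
               centers3d = list())
  sep <- 0
  for (h in c("L", "R")) {
    idx <- which(hemi == h)
    if (!length(idx)) next
    pole <- if (h == "L") poleL else poleR
    ctr <- colMeans(coords[idx, , drop = FALSE])
    rel <- sweep(coords[idx, , drop = FALSE], 2, ctr)
    rad <- sqrt(rowSums(rel^2))
    if (any(rad == 0)) stop("node coordinates must not coincide with the hemisphere centroid")
    u <- rel / rad
    R <- mean(rad)
    cpsi <- pmin(1, pmax(-1, as.vector(u %*% pole)))
    rho <- 2 * sin(acos(cpsi) / 2)          # Lambert closed form, unit sphere
    basis <- .tangentBasis(pole)
    tx <- as.vector(u %*% basis[1, ]); ty <- as.vector(u %*% basis[2, ])
    az <- sqrt(tx^2 + ty^2)
    bad <- which(az < 1e-12 & cpsi < 0)     # antipode: azimuth undefined
    if (length(bad)) {
      warning(sprintf("%d node(s) at the antipode of the %s pole placed on the map boundary",
                      length(bad), h))
      tx[bad] <- 1; ty[bad] <- 0; az[bad] <- 1; rho[bad] <- 2
    }
    ok <- az >= 1e-12
    dir <- cbind(ifelse(ok, tx / az, 1), ifelse(ok, ty / az, 0))
    out[idx, ] <- R * rho * dir
    meta$radii[h] <- R
    meta$centers3d[[h]] <- ctr
    sep <- max(sep, 2.2 * R)
  }
  # disjoint half-planes: shift hemispheres apart along map x
  shift <- c(L = -sep, R = +sep)
  for (h in c("L", "R")) {
    idx <- which(hemi == h)
    out[idx, 1] <- out[idx, 1] + shift[h]
  }
  centers <- rbind(L = c(shift["L"], 0), R = c(shift["R"], 0))
  dimnames(centers) <- list(c("L", "R"), NULL)
  new("SurfaceMap", coords2d = out, hemisphere = hemi,
      hemisphereCenters = centers, meta = meta)
}
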