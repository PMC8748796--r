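#' Configuration for the synthetic connectome generator
#'
#' Describes a synthetic, spatially embedded whole-cortex connectome with the
#' statistical structure the wave analyses rely on: nodes quasi-uniformly
#' covering two hemispheric sphere caps separated by a midline gap,
#' distance-decaying connection weights with a heavy-weighted hub subset,
#' mildly tortuous tract lengths, conduction delays at a fixed axonal
#' velocity, and seven spatially contiguous network parcels standing in for
#' the canonical resting-state networks.
#'
#' @param nNodes number of regions (default 468).
#' @param meanVolume mean region volume, mm^3 (default 2144; sd 399,
#'   truncated to the 753-3077 mm^3 range).
#' @param weightDecayLength exponential decay length of connection weight
#'   with distance, mm (default 30).
#' @param hubFraction proportion of nodes given a hub weight multiplier
#'   (default 0.2).
#' @param hubGain weight multiplier applied to hub nodes (default 3).
#' @param velocity axonal conduction velocity, m/s (default 10.8).
#' @param nNetworks number of contiguous network parcels (default 7).
#' @param tortuosity tract length excess over the straight line; tracts are
#'   curved, so L = d * (1 + tortuosity) (default 0.15).
#' @param sphereRadius hemisphere sphere radius, mm (default 60).
#' @param hemisphereGap distance between the two sphere centres, mm
#'   (default 70).
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return a \code{SyntheticConfig} object.
#' @export
syntheticConfig <- function(nNodes = 468L, meanVolume = 2144,
                            weightDecayLength = 30, hubFraction = 0.2,
                            hubGain = 3, velocity = 10.8, nNetworks = 7L,
                            tortuosity = 0.15, sphereRadius = 60,
                            hemisphereGap = 70, seed = 1L) {
  cfg <- list(nNodes = as.integer(nNodes), meanVolume = meanVolume,
              weightDecayLength = weightDecayLength,
              hubFraction = hubFraction, hubGain = hubGain,
              velocity = velocity, nNetworks = as.integer(nNetworks),
              tortuosity = tortuosity, sphereRadius = sphereRadius,
              hemisphereGap = hemisphereGap, seed = as.integer(seed))
  if (cfg$nNodes < 2L) stop("invalid config: nNodes must be >= 2")
  if (cfg$nNetworks < 2L) stop("invalid config: nNetworks must be >= 2")
  if (cfg$nNodes < cfg$nNetworks) {
    stop("invalid config: nNodes must be >= nNetworks")
  }
  if (cfg$velocity <= 0) stop("invalid config: velocity must be > 0")
  if (cfg$hubFraction < 0 || cfg$hubFraction > 1) {
    stop("invalid config: hubFraction must lie in [0, 1]")
  }
  structure(cfg, class = "SyntheticConfig")
}

# Quasi-uniform points on a lateral hemispheric cap: Fibonacci lattice in
# (cos psi, azimuth) with a small seeded jitter, expressed in the frame
# whose pole is the lateral direction of that hemisphere.
.capPoints <- function(m, pole, e1, e2, jitter = 0.25) {
  i <- seq_len(m)
  cpsi <- 1 - (i - 0.5) / m            # cos(angle from pole), in (0, 1)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  cpsi <- pmin(1, pmax(0, cpsi + stats::rnorm(m, 0, jitter / m)))
  phi <- phi + stats::rnorm(m, 0, jitter * 2 * pi / m)
  spsi <- sqrt(1 - cpsi^2)
  u <- outer(cpsi, pole) +
    outer(spsi * cos(phi), e1) + outer(spsi * sin(phi), e2)
  u
}

# Symmetric spatial adjacency used for parcel growing and contiguity checks:
# k nearest neighbours within each hemisphere plus one homotopic edge per
# node to its nearest contralateral node (callosal-like), so bilateral
# parcels remain connected.
#' Spatial adjacency graph of a connectome
#'
#' Symmetrised k-nearest-neighbour graph within each hemisphere, augmented
#' with one homotopic (nearest contralateral) edge per node. This is the
#' graph in which network parcels are grown and in which their spatial
#' contiguity is defined.
#'
#' @param net a \code{ConnectomeNetwork}, or a numeric n x 3 coordinate
#'   matrix together with `hemisphere`.
#' @param hemisphere character vector of "L"/"R" (ignored when `net` is a
#'   \code{ConnectomeNetwork}).
#' @param k neighbours per node within a hemisphere (default 6).
#' @return list of integer neighbour vectors, one per node.
#' @export
spatialAdjacency <- function(net, hemisphere = NULL, k = 6L) {
  if (is(net, "ConnectomeNetwork")) {
    coords <- nodeCoords(net); hemisphere <- hemispheres(net)
  } else {
    coords <- net
  }
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  adj <- vector("list", n)
  for (h in c("L", "R")) {
    idx <- which(hemisphere == h)
    other <- which(hemisphere != h)
    for (i in idx) {
      within <- idx[idx != i]
      kk <- min(k, length(within))
      nb <- within[order(d[i, within])[seq_len(kk)]]
      if (length(other)) nb <- c(nb, other[which.min(d[i, other])])
      adj[[i]] <- nb
    }
  }
  # symmetrise
  for (i in seq_len(n)) for (j in adj[[i]]) {
    if (!(i %in% adj[[j]])) adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Multi-source Dijkstra growth: each unlabelled node inherits the label of
# the finalised node it is first relaxed from, so every parcel is connected
# in the adjacency graph by construction.
.growParcels <- function(coords, adj, seeds) {
  n <- nrow(coords)
  dist <- rep(Inf, n); lab <- rep(NA_integer_, n); done <- rep(FALSE, n)
  dist[seeds] <- 0; lab[seeds] <- seq_along(seeds)
  for (step in seq_len(n)) {
    u <- which(!done)[which.min(dist[!done])]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (v in adj[[u]]) {
      if (done[v]) next
      w <- sqrt(sum((coords[u, ] - coords[v, ])^2))
      if (dist[u] + w < dist[v]) {
        dist[v] <- dist[u] + w
        lab[v] <- lab[u]
      }
    }
  }
  lab
}

# Farthest-point sampling for well-separated parcel seeds.
.farthestPoints <- function(coords, idx, m, start) {
  chosen <- start
  while (length(chosen) < m) {
    rest <- setdiff(idx, chosen)
    dmin <- vapply(rest, function(i) {
      min(colSums((t(coords[chosen, , drop = FALSE]) - coords[i, ])^2))
    }, numeric(1))
    chosen <- c(chosen, rest[which.max(dmin)])
  }
  chosen
}

#' Generate a synthetic spatially embedded connectome
#'
#' Builds a \code{ConnectomeNetwork} emulating a diffusion-MRI-derived
#' cortical connectome: nodes quasi-uniformly cover two hemispheric sphere
#' caps; weights decay exponentially with distance, are boosted for a hub
#' subset, divided by distance and by relative node volumes, then rescaled
#' to unit mean row sum; tract lengths exceed straight-line
#' distance by a fixed tortuosity; delays are tract length over conduction
#' velocity; network labels are grown from well-separated seeds so each of
#' the parcels is spatially contiguous (and bilateral through homotopic
#' adjacency).
#'
#' @param cfg a \code{SyntheticConfig} from [syntheticConfig()].
#' @return a \code{ConnectomeNetwork}.
#' @examples
#' net <- generateConnectome(syntheticConfig(nNodes = 60, seed = 1))
#' net
#' @export
generateConnectome <- function(cfg = syntheticConfig()) {
  if (!inherits(cfg, "SyntheticConfig")) stop("cfg must be a SyntheticConfig")
  set.seed(cfg$seed)
  n <- cfg$nNodes
  nL <- ceiling(n / 2); nR <- n - nL
  r <- cfg$sphereRadius
  cL <- c(-cfg$hemisphereGap / 2, 0, 0)
  cR <- c(+cfg$hemisphereGap / 2, 0, 0)
  uL <- .capPoints(nL, pole = c(-1, 0, 0), e1 = c(0, 1, 0), e2 = c(0, 0, 1))
  uR <- .capPoints(nR, pole = c(+1, 0, 0), e1 = c(0, -1, 0), e2 = c(0, 0, 1))
  coords <- rbind(sweep(r * uL, 2, cL, "+"), sweep(r * uR, 2, cR, "+"))
  hemi <- c(rep("L", nL), rep("R", nR))

  # volumes: truncated Gaussian matching empirical parcellation statistics
  vols <- stats::rnorm(n, cfg$meanVolume, 399)
  bad <- vols < 753 | vols > 3077
  while (any(bad)) {
    vols[bad] <- stats::rnorm(sum(bad), cfg$meanVolume, 399)
    bad <- vols < 753 | vols > 3077
  }

  hubs <- rep(1, n)
  nHub <- round(cfg$hubFraction * n)
  if (nHub > 0) hubs[sample.int(n, nHub)] <- cfg$hubGain

  d <- as.matrix(stats::dist(coords))
  w <- exp(-d / cfg$weightDecayLength) * outer(hubs, hubs)
  relVol <- vols / mean(vols)
  dpos <- d; diag(dpos) <- 1
  w <- w / dpos / outer(relVol, relVol)
  diag(w) <- 0
  w[w < 1e-6 * max(w)] <- 0          # drop numerically negligible tracts
  w <- (w + t(w)) / 2
  # normalise to unit mean row sum: the coupling constant then acts as the
  # effective per-node input rate (rad/s), independent of network size
  w <- w / mean(rowSums(w))

  L <- d * (1 + cfg$tortuosity)
  diag(L) <- 0
  dimnames(w) <- dimnames(L) <- NULL
  D <- L / (cfg$velocity * 1000)

  adj <- spatialAdjacency(coords, hemisphere = hemi, k = 6L)
  left <- which(hemi == "L")
  seeds <- .farthestPoints(coords, left, cfg$nNetworks,
                           start = left[sample.int(length(left), 1)])
  labels <- .growParcels(coords, adj, seeds)

  deg <- rowSums(w)
  deg <- deg / max(deg)

  new("ConnectomeNetwork", coords = coords, hemisphere = hemi, weights = w,
      tractLengths = L, delays = D, velocity = cfg$velocity, volumes = vols,
      networkLabels = as.integer(labels), degrees = deg)
}

#' Check spatial contiguity of network parcels
#'
#' Every label class must form one connected component in the spatial
#' adjacency graph (see [spatialAdjacency()]).
#'
#' @param net a \code{ConnectomeNetwork}.
#' @param k neighbours per node used to build the adjacency graph.
#' @return logical vector, one entry per label, TRUE when contiguous.
#' @export
parcelContiguity <- function(net, k = 6L) {
  adj <- spatialAdjacency(net, k = k)
  labels <- networkLabels(net)
  vapply(sort(unique(labels)), function(l) {
    memb <- which(labels == l)
    seen <- rep(FALSE, length(memb))
    names(seen) <- memb
    queue <- memb[1]; seen[1] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- intersect(adj[[u]], memb)
      newnb <- nb[!seen[as.character(nb)]]
      seen[as.character(newnb)] <- TRUE
      queue <- c(queue, newnb)
    }
    all(seen)
  }, logical(1))
}

#' Write a connectome to delimited text files
#'
#' Writes `weights.tsv`, `lengths.tsv` (plain N x N matrices) and
#' `nodes.tsv` (columns node_id, x, y, z, hemisphere, volume, label;
#' node_id is 0-based) to a directory.
#'
#' @param net a \code{ConnectomeNetwork}.
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
writeConnectome <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(edgeWeights(net), file.path(dir, "weights.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(tractLengths(net), file.path(dir, "lengths.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  nodes <- data.frame(node_id = seq_len(nNodes(net)) - 1L,
                      x = nodeCoords(net)[, 1], y = nodeCoords(net)[, 2],
                      z = nodeCoords(net)[, 3],
                      hemisphere = hemispheres(net),
                      volume = nodeVolumes(net),
                      label = networkLabels(net))
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load a connectome from delimited text files
#'
#' Delays are computed from the loaded tract lengths as L / v under a fixed
#' conduction-velocity assumption. Weighted degrees are recomputed from the
#' weight matrix and normalised to [0, 1].
#'
#' @param weightsPath TSV/CSV square weight matrix (no header).
#' @param lengthsPath TSV/CSV square tract-length matrix, mm (no header).
#' @param nodesPath node table with header: node_id, x, y, z, hemisphere,
#'   volume, label (0-based node_id).
#' @param velocity conduction velocity v, m/s.
#' @param labelsPath optional single-column file of labels overriding the
#'   `label` column of the node table.
#' @param tol symmetry tolerance relative to the largest entry.
#' @return a \code{ConnectomeNetwork}.
#' @export
loadConnectome <- function(weightsPath, lengthsPath, nodesPath, velocity,
                           labelsPath = NULL, tol = 1e-6) {
  readMat <- function(path, what) {
    m <- as.matrix(utils::read.table(path, sep = "", header = FALSE))
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) stop(sprintf("%s matrix is not square: %d x %d",
                                         what, nrow(m), ncol(m)))
    if (any(m < 0)) stop(sprintf("%s matrix has negative entries", what))
    if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
      stop(sprintf("%s matrix is asymmetric beyond tolerance", what))
    }
    (m + t(m)) / 2
  }
  w <- readMat(weightsPath, "weight")
  L <- readMat(lengthsPath, "tract-length")
  nodes <- utils::read.table(nodesPath, header = TRUE, sep = "",
                             stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "hemisphere", "volume", "label")
  if (!all(need %in% names(nodes))) {
    stop("node table must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(nodes) != nrow(w) || nrow(w) != nrow(L)) {
    stop(sprintf("shape mismatch: %d nodes, %d x %d weights, %d x %d lengths",
                 nrow(nodes), nrow(w), ncol(w), nrow(L), ncol(L)))
  }
  labels <- nodes$label
  if (!is.null(labelsPath)) {
    labels <- utils::read.table(labelsPath, header = FALSE)[[1]]
  }
  if (velocity <= 0) stop("velocity must be positive")
  deg <- rowSums(w)
  deg <- if (max(deg) > 0) deg / max(deg) else deg
  new("ConnectomeNetwork",
      coords = as.matrix(nodes[, c("x", "y", "z")]),
      hemisphere = as.character(nodes$hemisphere),
      weights = w, tractLengths = L, delays = L / (velocity * 1000),
      velocity = velocity, volumes = nodes$volume,
      networkLabels = as.integer(labels), degrees = deg)
}
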