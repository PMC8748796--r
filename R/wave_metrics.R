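# Headline statistics: UCI and the sequencing effect, phase-based network
# segmentation, relative-phase PCA, SSI slopes, grouping-size scan and
# permutation inference.

#' Unidirectional communication index
#'
#' For node j, the mean over partners k of
#' \eqn{0.5 \cos(\theta_j - \theta_k - \delta_{jk}) + 0.5}, where the
#' offset \eqn{\delta_{jk} = 2\pi f_0 \tau_{jk}} expresses the conduction
#' delay as a phase at the network's mean frequency. U_j is 1 when every
#' pair's phase lead exactly matches the offset that makes j's output
#' arrive in k's receptive phase (communication-through-coherence), 0 when
#' maximally misaligned. Invariant under global phase rotation.
#'
#' `literalDelayTerm = TRUE` switches to the offset \eqn{2\pi\tau_{jk}/f_0}.
#'
#' @param phasesSnapshot numeric vector of phases, radians.
#' @param delayMatrix N x N conduction delays, seconds.
#' @param f0 mean intrinsic frequency, Hz.
#' @param literalDelayTerm use tau / f0 instead of f0 * tau in the offset.
#' @return numeric vector of U_j values in [0, 1].
#' @export
uci <- function(phasesSnapshot, delayMatrix, f0, literalDelayTerm = FALSE) {
  n <- length(phasesSnapshot)
  stopifnot(all(dim(delayMatrix) == c(n, n)))
  off <- if (literalDelayTerm) 2 * pi * delayMatrix / f0
         else 2 * pi * f0 * delayMatrix
  d <- outer(phasesSnapshot, phasesSnapshot, "-") - off
  rowMeans(0.5 * cos(d) + 0.5)
}

#' Slope of UCI on intrinsic frequency
#'
#' Ordinary least-squares slope of per-node UCI values on per-node
#' intrinsic frequencies (units: per Hz), with the regression t-statistic.
#'
#' @param uciValues numeric vector of U_j.
#' @param freqs numeric vector of intrinsic frequencies f_j, Hz.
#' @return list with `slope` and `tValue`.
#' @export
uciSlope <- function(uciValues, freqs) {
  if (length(uciValues) < 3) stop("need at least 3 nodes")
  if (stats::var(freqs) == 0) {
    stop("undefined slope: zero variance in intrinsic frequencies")
  }
  fit <- stats::lm(uciValues ~ freqs)
  co <- summary(fit)$coefficients
  list(slope = unname(co["freqs", "Estimate"]),
       tValue = unname(co["freqs", "t value"]))
}

#' Sequencing effect: per-sample UCI slopes and their t-test
#'
#' Computes U_j at every retained snapshot, regresses it on that epoch's
#' intrinsic frequencies, and tests the per-sample slopes against zero with
#' a one-sample t-test. A positive mean slope means regions with faster
#' intrinsic frequencies occupy wave phases that favour outward
#' communication.
#'
#' @param traj a \code{PhaseTrajectory}.
#' @param net a \code{ConnectomeNetwork} (for the delay matrix).
#' @param f0 mean intrinsic frequency, Hz; defaults to the trajectory's
#'   configured value.
#' @param literalDelayTerm see [uci()].
#' @return list with `slopes` (per sample), `meanSlope`, `tValue`, `df`,
#'   `pValue`.
#' @export
sequencingEffect <- function(traj, net, f0 = NULL, literalDelayTerm = FALSE) {
  if (is.null(f0)) f0 <- traj@config$f0
  D <- delays(net)
  ph <- phases(traj); fr <- epochFreqs(traj)
  slopes <- vapply(seq_len(nrow(ph)), function(s) {
    uciSlope(uci(ph[s, ], D, f0, literalDelayTerm), fr[s, ])$slope
  }, numeric(1))
  tt <- stats::t.test(slopes)
  list(slopes = slopes, meanSlope = mean(slopes),
       tValue = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value)
}

# Per-sample pairwise Cohen's d between label groups, exactly per the
# pooled form d_ij = |mean(P_i) - mean(P_j)| /
# sqrt(((N_i-1) var(P_i) + (N_j-1) var(P_j)) / (N_i + N_j)).
# Vectorised over samples: relM is samples x nodes.
.pairwiseD <- function(relM, labels, groups) {
  k <- length(groups)
  ind <- sapply(groups, function(g) as.numeric(labels == g))
  Ni <- colSums(ind)
  mu <- relM %*% ind %*% diag(1 / Ni, k)            # S x k group means
  m2 <- (relM^2) %*% ind %*% diag(1 / Ni, k)
  va <- (m2 - mu^2) * rep(Ni / (Ni - 1), each = nrow(relM))  # sample var
  pairs <- utils::combn(k, 2)
  d <- matrix(NA_real_, nrow(relM), ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    pooled <- ((Ni[i] - 1) * va[, i] + (Ni[j] - 1) * va[, j]) / (Ni[i] + Ni[j])
    d[, p] <- abs(mu[, i] - mu[, j]) / sqrt(pooled)
  }
  list(d = d, pairs = pairs, means = mu, Ni = Ni)
}

#' Phase-based network segmentation
#'
#' Measures how traveling waves separate the relative-phase distributions
#' of the network parcels: per-sample pairwise Cohen's d between parcels
#' (pooled-variance form with an N_i + N_j denominator), a per-sample
#' one-way ANOVA F across parcels, and a label-permutation test of each
#' pair's time-averaged d with Benjamini-Hochberg FDR control. Relative
#' phases are treated as linear quantities; in the operating regime they
#' are centred at 0 with spread below pi.
#'
#' @param relPhaseMatrix samples x nodes matrix of relative phases, or a
#'   \code{PhaseTrajectory}.
#' @param labels integer parcel label per node.
#' @param nPerm label permutations (default 2000).
#' @param alpha FDR level for flagging significant pairs (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return list with `dMatrix` (time-averaged pairwise d), `pairTable`
#'   (pair, d, pValue, pAdjust, significant), `meanD`, `nullMeanD`
#'   (permutation distribution of the pair-averaged d), `anovaF` (per
#'   sample), `meanF`, `networkMeans` (samples x parcels), `groupSizes`.
#' @export
segmentation <- function(relPhaseMatrix, labels, nPerm = 2000,
                         alpha = 0.05, seed = 1L) {
  relM <- if (is(relPhaseMatrix, "PhaseTrajectory")) relPhases(relPhaseMatrix)
          else as.matrix(relPhaseMatrix)
  labels <- as.integer(labels)
  groups <- sort(unique(labels))
  if (any(tabulate(match(labels, groups)) < 2)) {
    stop("every network parcel must contain at least 2 nodes")
  }
  obs <- .pairwiseD(relM, labels, groups)
  dBar <- colMeans(obs$d)
  if (any(!is.finite(dBar))) {
    warning("infinite Cohen's d: zero pooled variance in some pair")
  }
  k <- length(groups)
  dMatrix <- matrix(0, k, k, dimnames = list(groups, groups))
  for (p in seq_len(ncol(obs$pairs))) {
    dMatrix[obs$pairs[1, p], obs$pairs[2, p]] <- dBar[p]
    dMatrix[obs$pairs[2, p], obs$pairs[1, p]] <- dBar[p]
  }
  fvals <- vapply(seq_len(nrow(relM)), function(s) {
    stats::oneway.test(relM[s, ] ~ factor(labels), var.equal = TRUE)$statistic
  }, numeric(1))
  set.seed(seed)
  nullPair <- matrix(NA_real_, nPerm, ncol(obs$pairs))
  for (b in seq_len(nPerm)) {
    nullPair[b, ] <- colMeans(.pairwiseD(relM, sample(labels), groups)$d)
  }
  if (nPerm > 0) {
    pPair <- vapply(seq_len(ncol(obs$pairs)), function(p) {
      (1 + sum(nullPair[, p] >= dBar[p])) / (nPerm + 1)
    }, numeric(1))
    pAdj <- stats::p.adjust(pPair, method = "BH")
  } else {
    pPair <- pAdj <- rep(NA_real_, ncol(obs$pairs))
  }
  pairTable <- data.frame(i = groups[obs$pairs[1, ]],
                          j = groups[obs$pairs[2, ]],
                          d = dBar, pValue = pPair, pAdjust = pAdj,
                          significant = pAdj < alpha)
  list(dMatrix = dMatrix, pairTable = pairTable, meanD = mean(dBar),
       nullMeanD = rowMeans(nullPair), anovaF = fvals, meanF = mean(fvals),
       networkMeans = obs$means, groupSizes = obs$Ni)
}

#' Principal components of the relative-phase pattern
#'
#' Linearises relative phases (valid because they are centred at zero with
#' a single-peaked, sub-pi-wide distribution in the operating regime),
#' centres each node over samples, and extracts spatial principal
#' components. Warns when more than 5% of samples have a bulk phase spread
#' (central 98% range, robust to isolated straggler nodes) of pi or more:
#' linearisation is unsafe there.
#'
#' @param relPhaseMatrix samples x nodes matrix of relative phases, or a
#'   \code{PhaseTrajectory}.
#' @return list with `components` (nodes x components), `explained`
#'   (variance fractions), `scores` (samples x components), `spreadOK`.
#' @export
relativePhasePCA <- function(relPhaseMatrix) {
  relM <- if (is(relPhaseMatrix, "PhaseTrajectory")) relPhases(relPhaseMatrix)
          else as.matrix(relPhaseMatrix)
  if (nrow(relM) < 2) stop("need at least 2 samples")
  spread <- apply(relM, 1, function(x) {
    diff(stats::quantile(x, c(0.01, 0.99), names = FALSE))
  })
  fracWide <- mean(spread >= pi)
  if (fracWide > 0.05) {
    warning(sprintf("phase spread >= pi in %.0f%% of samples: linearisation unsafe",
                    100 * fracWide))
  }
  pc <- stats::prcomp(relM, center = TRUE, scale. = FALSE)
  list(components = pc$rotation, explained = pc$sdev^2 / sum(pc$sdev^2),
       scores = pc$x, spreadOK = fracWide <= 0.05)
}

#' Slope of SSI on intrinsic frequency, per radius
#'
#' For a centre node, regresses the per-sample source-sink index at each
#' radius on the centre's intrinsic frequency. Large positive slopes at
#' small radii mean that epochs in which the centre runs fast produce
#' outward radial waves (a phase cone) around it.
#'
#' @param map a \code{SurfaceMap}.
#' @param field a \code{WaveField}.
#' @param traj a \code{PhaseTrajectory}.
#' @param center node index.
#' @param radii annulus radii, mm.
#' @param dr annulus half-width, mm.
#' @param minSamples minimum valid samples per radius (default 20).
#' @return data.frame with radius, slope (rad/Hz), nValid.
#' @export
ssiSlope <- function(map, field, traj, center, radii, dr = 10,
                     minSamples = 20L) {
  f <- epochFreqs(traj)[, center]
  res <- lapply(radii, function(r) {
    s <- ssiSeries(map, field, center, r, dr = dr)
    ok <- is.finite(s)
    slope <- if (sum(ok) >= minSamples && stats::var(f[ok]) > 0) {
      unname(stats::coef(stats::lm(s[ok] ~ f[ok]))[2])
    } else NA_real_
    data.frame(radius = r, slope = slope, nValid = sum(ok))
  })
  do.call(rbind, res)
}

#' SSI slope versus node degree across centres
#'
#' @param map a \code{SurfaceMap}.
#' @param field a \code{WaveField}.
#' @param traj a \code{PhaseTrajectory}.
#' @param net a \code{ConnectomeNetwork}.
#' @param r annulus radius, mm.
#' @param centers node indices (default all).
#' @inheritParams ssiSlope
#' @return data.frame with node, degree, slope, nValid.
#' @export
ssiSlopeByDegree <- function(map, field, traj, net, r, dr = 10,
                             centers = seq_len(nNodes(net)),
                             minSamples = 20L) {
  do.call(rbind, lapply(centers, function(j) {
    row <- ssiSlope(map, field, traj, j, radii = r, dr = dr,
                    minSamples = minSamples)
    data.frame(node = j, degree = nodeDegrees(net)[j], slope = row$slope,
               nValid = row$nValid)
  }))
}

#' Grouping-size scan: frequency-to-phase slope versus pooled area
#'
#' For each circular grouping area around a centre, pools (f_j, theta'_j)
#' over member nodes and samples and fits the OLS slope of relative phase
#' on intrinsic frequency. The optimal area is the one maximising |slope|;
#' it is undefined (NA) when no area shows any frequency dependence.
#'
#' @param map a \code{SurfaceMap}.
#' @param traj a \code{PhaseTrajectory}.
#' @param center node index.
#' @param areas grouping areas, cm^2 (default 12 log-spaced values from 10
#'   to 400).
#' @param minNodes minimum member nodes per disk (default 5).
#' @return list with `table` (area, radius, slope, nNodes) and
#'   `optimalArea` (cm^2, NA when undefined).
#' @export
groupingScan <- function(map, traj, center,
                         areas = exp(seq(log(10), log(400), length.out = 12)),
                         minNodes = 5L) {
  x <- mapCoords(map)
  dist <- sqrt(rowSums(sweep(x, 2, x[center, ])^2))
  relM <- relPhases(traj); frM <- epochFreqs(traj)
  rows <- lapply(areas, function(a) {
    rad <- sqrt(a * 100 / pi)                  # cm^2 -> mm^2 -> radius mm
    memb <- which(dist <= rad)
    if (length(memb) < minNodes) {
      return(data.frame(area = a, radius = rad, slope = NA_real_,
                        nNodes = length(memb)))
    }
    f <- as.vector(frM[, memb]); ph <- as.vector(relM[, memb])
    slope <- if (stats::var(f) > 0) {
      unname(stats::coef(stats::lm(ph ~ f))[2])
    } else NA_real_
    data.frame(area = a, radius = rad, slope = slope, nNodes = length(memb))
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$slope) & abs(tab$slope) > 0
  optimal <- if (any(ok)) tab$area[ok][which.max(abs(tab$slope[ok]))] else NA_real_
  list(table = tab, optimalArea = optimal)
}

#' Map of optimal grouping areas across centres
#'
#' @inheritParams groupingScan
#' @param centers node indices (default all).
#' @return data.frame with node, optimalArea (cm^2), maxAbsSlope.
#' @export
groupingScanMap <- function(map, traj,
                            areas = exp(seq(log(10), log(400), length.out = 12)),
                            centers = seq_len(nNodes(map)), minNodes = 5L) {
  do.call(rbind, lapply(centers, function(j) {
    sc <- groupingScan(map, traj, j, areas = areas, minNodes = minNodes)
    mx <- suppressWarnings(max(abs(sc$table$slope), na.rm = TRUE))
    data.frame(node = j, optimalArea = sc$optimalArea,
               maxAbsSlope = ifelse(is.finite(mx), mx, NA_real_))
  }))
}

#' Frequency dependence of the local phase gradient, with permutation test
#'
#' At a centre location, regresses the per-sample signed component of the
#' fitted phase gradient along the location's mean propagation direction on
#' the mean intrinsic frequency of the grouped (disk) nodes. The null is
#' built by shuffling whole epoch frequency vectors across epochs (the
#' gradient series is left untouched), giving a two-sided permutation p.
#'
#' @param map a \code{SurfaceMap}.
#' @param traj a \code{PhaseTrajectory}.
#' @param field a \code{WaveField}.
#' @param center node index.
#' @param area grouping area, cm^2 (default 100).
#' @param nPerm permutations (default 2000).
#' @param seed RNG seed for the permutations.
#' @param minNodes minimum member nodes in the disk.
#' @return list with `slope`, `pValue`, `nullSlopes`, `nNodes`, `nValid`;
#'   NA slope when the centre has no defined mean direction.
#' @export
gradientFrequencySlope <- function(map, traj, field, center, area = 100,
                                   nPerm = 2000, seed = 1L, minNodes = 5L) {
  x <- mapCoords(map)
  dist <- sqrt(rowSums(sweep(x, 2, x[center, ])^2))
  rad <- sqrt(area * 100 / pi)
  memb <- which(dist <= rad)
  if (length(memb) < minNodes) stop("grouping disk holds too few nodes")
  frM <- epochFreqs(traj)
  fbar <- rowMeans(frM[, memb, drop = FALSE])
  if (stats::var(fbar) == 0) stop("zero variance in grouped intrinsic frequencies")
  md <- meanDirectionMap(field)
  if (!md$defined[center]) {
    return(list(slope = NA_real_, pValue = NA_real_, nullSlopes = numeric(0),
                nNodes = length(memb), nValid = 0L))
  }
  u <- c(cos(md$meanDir[center]), sin(md$meanDir[center]))
  comp <- field@gx[, center] * u[1] + field@gy[, center] * u[2]
  ok <- is.finite(comp)
  olsSlope <- function(y, xv) {
    xv <- xv - mean(xv)
    sum(xv * y) / sum(xv^2)
  }
  slope <- olsSlope(comp[ok], fbar[ok])
  set.seed(seed)
  # permuting whole epoch frequency vectors across epochs permutes the
  # per-epoch disk means; reuse them rather than re-averaging each draw
  nullSlopes <- vapply(seq_len(nPerm), function(b) {
    fb <- fbar[sample(length(fbar))]
    olsSlope(comp[ok], fb[ok])
  }, numeric(1))
  p <- (1 + sum(abs(nullSlopes) >= abs(slope))) / (nPerm + 1)
  list(slope = slope, pValue = p, nullSlopes = nullSlopes,
       nNodes = length(memb), nValid = sum(ok))
}

#' Correlation between network-mean relative phase and network-mean degree
#'
#' Pools relative phases over samples within each parcel and correlates the
#' parcel means with parcel-mean weighted node degree (Pearson). Hub-heavy
#' parcels sitting in late wave phases give a negative correlation.
#'
#' @param traj a \code{PhaseTrajectory}.
#' @param net a \code{ConnectomeNetwork}.
#' @return list with `r`, `tValue`, `df`, `pValue`, `networkPhase`,
#'   `networkDegree`.
#' @export
networkPhaseDegreeCor <- function(traj, net) {
  labels <- networkLabels(net)
  groups <- sort(unique(labels))
  relM <- relPhases(traj)
  phBar <- vapply(groups, function(g) mean(relM[, labels == g]), numeric(1))
  degBar <- vapply(groups, function(g) mean(nodeDegrees(net)[labels == g]),
                   numeric(1))
  ct <- stats::cor.test(phBar, degBar)
  list(r = unname(ct$estimate), tValue = unname(ct$statistic),
       df = unname(ct$parameter), pValue = ct$p.value,
       networkPhase = phBar, networkDegree = degBar)
}
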