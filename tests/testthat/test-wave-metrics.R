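# UCI, segmentation, PCA, grouping scan and permutation machinery.

test_that("UCI reaches its extremes at delay-matched and anti-matched lags", {
  set.seed(2)
  n <- 6
  tau <- matrix(runif(n * n, 0, 0.02), n, n); tau <- (tau + t(tau)) / 2
  diag(tau) <- 0
  f0 <- 10
  off <- 2 * pi * f0 * tau
  # aligned case for node 1: theta_1 - theta_k = off_1k  =>  theta_k = -off_1k
  u1 <- uci(-off[1, ], tau, f0)[1]
  expect_equal(u1, 1, tolerance = 1e-12)
  u0 <- uci(wrapAngle(-off[1, ] + c(0, rep(pi, n - 1))), tau, f0)[1]
  # k = j term still contributes cos(0) = 1, the other n-1 give 0
  expect_equal(u0, 1 / n, tolerance = 1e-12)
})

test_that("UCI matches a hand-evaluated three-node case", {
  f0 <- 10
  tau <- matrix(0, 3, 3)
  tau[1, 2] <- tau[2, 1] <- 0.1 / (2 * pi * f0)   # offset 0.1 rad
  tau[1, 3] <- tau[3, 1] <- 0.2 / (2 * pi * f0)   # offset 0.2 rad
  th <- c(0, 0.4, 0.9)
  got <- uci(th, tau, f0)[1]
  # by hand: (1/3) [1 + (0.5 cos(-0.4 - 0.1) + 0.5) + (0.5 cos(-0.9 - 0.2) + 0.5)]
  expect_equal(got, (1 + 0.5 * cos(0.5) + 0.5 + 0.5 * cos(1.1) + 0.5) / 3,
               tolerance = 1e-12)
  expect_equal(got, 0.8885298, tolerance = 1e-7)
})

test_that("UCI is invariant under global phase rotation", {
  set.seed(3)
  n <- 12
  tau <- matrix(runif(n * n, 0, 0.03), n, n); tau <- (tau + t(tau)) / 2
  diag(tau) <- 0
  th <- runif(n, -pi, pi)
  expect_equal(uci(th, tau, 10), uci(wrapAngle(th + 2.2), tau, 10),
               tolerance = 1e-12)
})

test_that("UCI slope handles exact, flat and degenerate inputs", {
  f <- c(9, 10, 11, 12)
  expect_equal(suppressWarnings(uciSlope(rep(0.5, 4), f)$slope), 0,
               tolerance = 1e-12)
  expect_equal(suppressWarnings(uciSlope(0.05 * f + 0.1, f)$slope), 0.05,
               tolerance = 1e-12)
  expect_error(uciSlope(c(0.1, 0.2, 0.3), rep(10, 3)), "zero variance")
})

test_that("Cohen's d matches the printed pooled form and its invariances", {
  relM <- rbind(c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7))
  labels <- c(1, 1, 1, 2, 2, 2)
  seg <- segmentation(relM, labels, nPerm = 0)
  expect_equal(seg$dMatrix[1, 2], 0.4 / sqrt((2 * 0.01 + 2 * 0.01) / 6),
               tolerance = 1e-12)
  # identical groups give d = 0
  segSame <- segmentation(rbind(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3)), labels,
                          nPerm = 0)
  expect_equal(segSame$dMatrix[1, 2], 0, tolerance = 1e-12)
  # scale-free: doubling all deviations leaves d unchanged
  seg2 <- segmentation(2 * relM, labels, nPerm = 0)
  expect_equal(seg2$dMatrix[1, 2], seg$dMatrix[1, 2], tolerance = 1e-12)
})

test_that("label shuffling destroys group separation", {
  set.seed(21)
  S <- 30; n <- 60
  labels <- rep(1:3, each = n / 3)
  relM <- matrix(rnorm(S * n, rep(c(-0.5, 0, 0.5), each = n / 3)[col(matrix(0, S, n))], 0.2), S, n)
  relM <- t(apply(relM, 1, function(x) x - mean(x)))
  seg <- segmentation(relM, labels, nPerm = 300, seed = 2)
  expect_gt(seg$meanD, quantile(seg$nullMeanD, 0.95))
  expect_true(all(seg$pairTable$significant))
  # shuffled labels show no separation beyond the null
  segNull <- segmentation(relM, sample(labels), nPerm = 300, seed = 3)
  expect_lt(segNull$meanD, quantile(segNull$nullMeanD, 0.99))
})

test_that("relative-phase PCA recovers a planted rank-1 spatial pattern", {
  set.seed(8)
  S <- 80; n <- 50
  u <- sin(seq_len(n) / 4); u <- u - mean(u); u <- u / sqrt(sum(u^2))
  c_t <- rnorm(S, 0, 0.5)
  relM <- outer(c_t, u) + matrix(rnorm(S * n, 0, 0.005), S, n)
  pca <- relativePhasePCA(relM)
  expect_gt(pca$explained[1], 0.98)
  expect_gt(abs(cor(pca$components[, 1], u)), 0.999)
  # duplicated sample set: identical components
  pca2 <- relativePhasePCA(rbind(relM, relM))
  expect_equal(abs(cor(pca2$components[, 1], pca$components[, 1])), 1,
               tolerance = 1e-9)
  # white noise: no dominant component
  noise <- matrix(rnorm(100 * n, 0, 0.1), 100, n)
  expect_lt(relativePhasePCA(noise)$explained[1], 0.08)
  expect_warning(relativePhasePCA(matrix(runif(20 * n, -pi, pi), 20, n)),
                 "spread")
})

test_that("SSI slope is zero without coupling and recovers a planted one", {
  map <- gridMap(nx = 16, ny = 16)
  n <- nNodes(map)
  x <- mapCoords(map)
  center <- which.min(rowSums(sweep(x, 2, colMeans(x))^2))
  S <- 60
  set.seed(4)
  f <- matrix(rnorm(S * n, 10, 0.5), S, n)
  dx <- sweep(x, 2, x[center, ])
  rr <- sqrt(rowSums(dx^2)); rr[center] <- 1
  ur <- dx / rr
  # planted: outward wave strength proportional to the centre's detuning
  gx <- gy <- matrix(0, S, n)
  for (s in seq_len(S)) {
    beta <- 0.1 * (f[s, center] - 10)
    gx[s, ] <- -beta * ur[, 1]
    gy[s, ] <- -beta * ur[, 2]
  }
  traj <- syntheticTrajectory(matrix(0, S, n) + rnorm(S * n, 0, 0.1), f)
  fld <- new("WaveField", gx = gx, gy = gy, speeds = gx, dirX = gx,
             dirY = gy, windowSigma = 20)
  out <- ssiSlope(map, fld, traj, center, radii = 30)
  # S(r) = mean((x_k - x_j) . (-g)) = beta * mean(r) ~ 0.1 (f - 10) * 30
  expect_equal(out$slope, 3, tolerance = 0.1)
  fld0 <- new("WaveField", gx = gx * 0, gy = gy * 0, speeds = gx,
              dirX = gx, dirY = gy, windowSigma = 20)
  expect_equal(ssiSlope(map, fld0, traj, center, radii = 30)$slope, 0,
               tolerance = 1e-12)
})

test_that("grouping scan finds the planted spatial coupling scale", {
  map <- gridMap(nx = 26, ny = 26, spacing = 10, jitter = 1)
  n <- nNodes(map)
  x <- mapCoords(map)
  centers <- c(which.min(rowSums(sweep(x, 2, c(70, 70))^2)),
               which.min(rowSums(sweep(x, 2, c(200, 200))^2)))
  rhos <- c(45, 80)                           # planted extents, mm
  S <- 40
  set.seed(14)
  f <- matrix(rnorm(S * n, 10, 0.5), S, n)
  ph <- matrix(0, S, n)
  for (i in 1:2) {
    rr <- sqrt(rowSums(sweep(x, 2, x[centers[i], ])^2))
    w <- ifelse(rr <= rhos[i], rr / rhos[i], 0)
    ph <- ph + t(t(f - 10) * w) * 0.3
  }
  traj <- syntheticTrajectory(ph, f)
  areas <- exp(seq(log(20), log(600), length.out = 24))
  for (i in 1:2) {
    sc <- groupingScan(map, traj, centers[i], areas = areas)
    expected <- pi * rhos[i]^2 / 100          # cm^2
    expect_equal(log(sc$optimalArea), log(expected), tolerance = 0.15)
  }
  # frequency-independent phases: all slopes 0, optimum undefined
  flat <- syntheticTrajectory(matrix(0.3, S, n), f)
  scFlat <- groupingScan(map, traj = flat, centers[1], areas = areas)
  expect_true(all(abs(scFlat$table$slope) < 1e-12 | is.na(scFlat$table$slope)))
  expect_true(is.na(scFlat$optimalArea))
})

test_that("gradient-frequency slope has calibrated permutation inference", {
  map <- gridMap(nx = 10, ny = 10)
  n <- nNodes(map)
  S <- 40
  set.seed(6)
  f <- matrix(rnorm(S * n, 10, 0.5), S, n)
  # planted coupling: gradient component follows the disk-mean frequency
  x <- mapCoords(map)
  center <- which.min(rowSums(sweep(x, 2, colMeans(x))^2))
  memb <- which(sqrt(rowSums(sweep(x, 2, x[center, ])^2)) <=
                  sqrt(100 * 100 / pi))
  fbar <- rowMeans(f[, memb])
  gx <- matrix(rnorm(S * n, 0, 0.002), S, n)
  gx[, center] <- 0.02 * (fbar - 10) + rnorm(S, 0, 0.002)
  gy <- matrix(rnorm(S * n, 0, 1e-4), S, n)
  traj <- syntheticTrajectory(matrix(rnorm(S * n, 0, 0.1), S, n), f)
  fld <- syntheticField(gx + 0.05, gy)        # mean offset defines direction
  out <- gradientFrequencySlope(map, traj, fld, center, area = 100,
                                nPerm = 500, seed = 9)
  expect_lt(out$pValue, 0.05)
  expect_error(gradientFrequencySlope(map, syntheticTrajectory(
    matrix(rnorm(S * n, 0, 0.1), S, n), matrix(10, S, n)), fld, center),
    "zero variance")
})

test_that("faster regions hold earlier wave phases across epochs", {
  run <- ciRun()
  relM <- relPhases(run$traj); fM <- epochFreqs(run$traj)
  slopes <- vapply(seq_len(nrow(relM)), function(s) {
    unname(coef(lm(relM[s, ] ~ fM[s, ]))[2])
  }, numeric(1))
  # the faster oscillator leads (two-oscillator closed form fixes the sign)
  expect_gte(mean(slopes > 0), 0.9)
})

test_that("network-mean phase anticorrelates with network-mean degree", {
  run <- ciRun()
  out <- networkPhaseDegreeCor(run$traj, run$net)
  expect_lt(out$r, 0)
  expect_length(out$networkPhase, 7)
})
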