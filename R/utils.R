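# Small angular and RNG helpers shared across modules.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector or matrix of angles, radians.
#' @return object of the same shape with every element in (-pi, pi].
#' @export
wrapAngle <- function(x) {
  out <- -((-x + pi) %% (2 * pi) - pi)
  out[out == -pi] <- pi
  out
}

#' Circular mean argument of a set of angles
#'
#' Argument of the mean unit phasor. Errors when the resultant vanishes
#' (perfectly balanced phases have no defined mean direction).
#'
#' @param x numeric vector of angles, radians.
#' @param tol resultant lengths below `tol` are treated as zero.
#' @return scalar angle in (-pi, pi].
#' @export
circularMean <- function(x, tol = 1e-12) {
  z <- mean(exp(1i * x))
  if (Mod(z) < tol) {
    stop("circular mean undefined: resultant length is zero")
  }
  Arg(z)
}

# Circular (geodesic) distance between angles, in [0, pi].
circularDistance <- function(a, b) {
  abs(wrapAngle(a - b))
}

# Derive named integer sub-seeds from one root seed so that independent
# stochastic stages (connectome, schedule, initial phases, permutations)
# do not share streams. Kept below 2^31 - 1.
subSeeds <- function(seed, names) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  names(s) <- names
  s
}
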