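#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the delay-coupled phase-oscillator network
//
//   dtheta_j/dt = omega_j(t) + lambda * sum_k w_jk sin(theta_k(t - tau_jk) - theta_j(t))
//
// with a ring-buffer history of length max delay. Intrinsic angular
// frequencies are piecewise constant over epochs (one row of `omega` per
// epoch). Pre-t=0 history extrapolates each node backward at its initial
// intrinsic rate. Snapshots (wrapped phase and instantaneous right-hand
// side) are recorded at the requested global step indices.
//
// weights:     N x N, nonnegative, zero diagonal
// delaySteps:  N x N integer, delays rounded to steps of dt
// omega:       nEpochs x N, rad/s
// theta0:      N initial phases
// sampleSteps: 0-based global step indices at which to record
// sampleEpoch: 0-based epoch index of each sample (selects omega row)
// [[Rcpp::export]]
List kuramotoEulerCpp(NumericMatrix weights, IntegerMatrix delaySteps,
                      NumericMatrix omega, NumericVector theta0,
                      double dt, int stepsPerEpoch, double lambda,
                      IntegerVector sampleSteps, IntegerVector sampleEpoch) {
  const int n = weights.nrow();
  const int nEpochs = omega.nrow();
  const int totalSteps = nEpochs * stepsPerEpoch;
  const int nSamples = sampleSteps.size();

  int maxDelay = 0;
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < n; ++k)
      if (weights(j, k) > 0.0 && delaySteps(j, k) > maxDelay)
        maxDelay = delaySteps(j, k);
  const int B = maxDelay + 1;

  // adjacency lists over nonzero weights
  std::vector< std::vector<int> > nbr(n);
  std::vector< std::vector<double> > nw(n);
  std::vector< std::vector<int> > nd(n);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < n; ++k)
      if (k != j && weights(j, k) > 0.0) {
        nbr[j].push_back(k);
        nw[j].push_back(weights(j, k));
        nd[j].push_back(delaySteps(j, k));
      }

  // ring buffer: row (s % B) holds theta at step s (steps may be negative
  // conceptually; history rows are pre-filled by backward extrapolation)
  std::vector<double> buf((size_t)B * n);
  for (int s = 0; s <= maxDelay; ++s) {
    // step index -s  ->  buffer row ((-s) mod B)
    int row = ((-s) % B + B) % B;
    for (int j = 0; j < n; ++j)
      buf[(size_t)row * n + j] = theta0[j] - omega(0, j) * s * dt;
  }

  // map global step -> sample row (-1 if none)
  std::vector<int> sampleAt(totalSteps, -1);
  for (int i = 0; i < nSamples; ++i) {
    int s = sampleSteps[i];
    if (s < 0 || s >= totalSteps) stop("sample step out of range");
    sampleAt[s] = i;
  }

  NumericMatrix thetaOut(nSamples, n), rateOut(nSamples, n);
  std::vector<double> rhs(n);

  for (int s = 0; s < totalSteps; ++s) {
    const int epoch = s / stepsPerEpoch;
    const int cur = s % B;
    const double* th = &buf[(size_t)cur * n];
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      const double tj = th[j];
      const std::vector<int>& kk = nbr[j];
      const std::vector<double>& ww = nw[j];
      const std::vector<int>& dd = nd[j];
      const size_t m = kk.size();
      for (size_t q = 0; q < m; ++q) {
        int row = ((s - dd[q]) % B + B) % B;
        acc += ww[q] * std::sin(buf[(size_t)row * n + kk[q]] - tj);
      }
      rhs[j] = omega(epoch, j) + lambda * acc;
    }
    const int samp = sampleAt[s];
    if (samp >= 0) {
      const double twopi = 2.0 * M_PI;
      for (int j = 0; j < n; ++j) {
        double w = th[j] - twopi * std::floor((th[j] + M_PI) / twopi);
        if (w > M_PI) w -= twopi;
        if (w <= -M_PI) w += twopi;
        thetaOut(samp, j) = w;
        rateOut(samp, j) = rhs[j];
      }
    }
    const int nxt = (s + 1) % B;
    double* thNext = &buf[(size_t)nxt * n];
    for (int j = 0; j < n; ++j) {
      double v = th[j] + dt * rhs[j];
      if (!std::isfinite(v))
        stop("integration diverged: non-finite phase at t = %.4f s (node %d)",
             (s + 1) * dt, j + 1);
      thNext[j] = v;
    }
  }

  return List::create(Named("phases") = thetaOut,
                      Named("instRates") = rateOut);
}
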