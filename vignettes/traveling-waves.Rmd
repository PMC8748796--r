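---
title: "Traveling waves from delay-coupled cortical oscillators: model, metrics and design choices"
author: "cortexwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling waves from delay-coupled cortical oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Each cortical region j carries a phase oscillator

$$\frac{d\theta_j}{dt} \;=\; \omega_j(t) \;+\; \lambda \sum_{k=1}^{N} w_{jk}\,
\sin\!\big(\theta_k(t-\tau_{jk}) - \theta_j(t)\big),$$

with symmetric nonnegative coupling weights $w_{jk}$, pairwise conduction
delays $\tau_{jk} = L_{jk}/v$ (tract length over a fixed axonal velocity),
and intrinsic angular frequencies $\omega_j = 2\pi f_j$. The intrinsic
frequencies are redrawn independently from Gaussian$(f_0, \sigma_f)$ every
0.5 s — the model's stand-in for state changes in local regions — and one
analysis snapshot is retained 0.3 s after each redraw, once a 1 s startup
transient has been discarded. Phases carry no stochastic noise; all
variability enters through the frequency schedule and initial conditions.

In this regime, weakly heterogeneous oscillators synchronise with lags
ordered by their detunings (the two-oscillator fixed point
$\sin\Delta\theta = 2\pi\Delta f / 2\lambda w$ generalises: the faster
oscillator leads), while the conduction delays impose a spatial phase
gradient, i.e. traveling waves on the cortical surface. The package
quantifies the two functional consequences: **segmentation** (waves group
spatially contiguous regions into bands of similar phase, separating
large-scale networks) and **sequencing** (within the wave, regions are
ordered by intrinsic frequency, which — by communication-through-coherence
— aligns phase leads with conduction delays and favours unidirectional
information flow from faster to slower regions).

## The synthetic connectome

Analyses of the real system use a diffusion-MRI connectome (hundreds of
contiguous gray-matter parcels, streamline-count weights, tract lengths,
resting-state-network labels). `generateConnectome()` emulates the
statistical structure those analyses rely on without any data download:

* **Geometry.** N nodes (default 468) quasi-uniformly cover two lateral
  hemispheric caps (Fibonacci lattice plus seeded jitter) of radius 60 mm,
  centres 70 mm apart. Node volumes are Gaussian (mean 2144 mm^3, sd 399,
  truncated to 753-3077 mm^3), matching a random cortical parcellation.
* **Weights.** $w_{jk} \propto e^{-d_{jk}/\ell}\, g_j g_k / (d_{jk}\,
  \tilde v_j \tilde v_k)$ with decay length $\ell = 30$ mm, hub gain
  $g = 3$ on a random 20% subset, division by distance and by relative
  node volumes. This preserves the two properties the analyses use:
  distance-dependent coupling and degree heterogeneity (hubs).
* **Normalisation.** Weights are rescaled to unit mean row sum, so the
  coupling constant $\lambda$ is the effective per-node input rate in
  rad/s, independent of N. This keeps one $\lambda$ meaningful across the
  reduced and full problem sizes.
* **Tract lengths and delays.** $L = d\,(1 + 0.15)$ — tracts are curved,
  so lengths mildly exceed the straight line; the exact tortuosity is
  immaterial to the properties tested. $D = L/v$ with $v = 10.8$ m/s.
  (With these numbers the mean delay is close to 10 ms; note that a mean
  tract length of 108.3 mm at 10.8 m/s arithmetically gives 10 ms, not
  6 ms.)
* **Network labels.** Seven parcels grown by multi-source Dijkstra
  expansion from well-separated left-hemisphere seeds over a spatial
  adjacency graph (within-hemisphere k-nearest-neighbour edges plus one
  homotopic edge per node). Growth through finalised neighbours makes
  every parcel connected by construction, and the homotopic edges make
  parcels bilateral, like empirical resting-state networks.
* **Thalamus.** Not specially modelled: excluding it changes little in
  the real system, so all nodes are treated homogeneously.

What the generator does **not** emulate: true streamline-count weight
distributions, subject variability, cortical folding, and the exact
spatial layout of empirical resting-state networks. Passing tests
therefore show that the *method* behaves correctly on networks with the
assumed statistical structure — not that any specific empirical brain
produces identical numbers.

## Choice of the coupling default

The weight normalisation of the original connectome (streamline counts
divided by length and volume) has no stated scale, so the literature value
of its coupling constant does not translate numerically. The package's
default, $\lambda = 10$ rad/s, was fixed once by a calibration scan
(N = 150, 40 epochs, $\lambda \in \{5, 10, 20, 40, 80\}$) against the
regime the real-connectome study reports: order parameter in the partially
synchronised range (R about 0.5-0.7), median propagation speed inside the
1-10 m/s axonal window, a clearly positive sequencing slope, and a
dominant first principal component of the relative phases. $\lambda = 10$
matched that profile best (R = 0.66, median speed 5.3 m/s, UCI slope
+0.07, PC1 = 46%, degree-phase correlation -0.79) and the surrounding
values show the same qualitative behaviour, so conclusions do not hinge on
the exact choice. The parameter sweep driver (`runSweep()`) makes the
dependence explicit.

## Wave-field estimation

All spatial analyses run on a 2-D map produced by Lambert's azimuthal
equal-area projection (`projectSurface()`), applied per hemisphere about a
lateral, C3/C4-like pole after radially normalising nodes to the
hemisphere sphere. Equal-area is the property that matters: annulus
areas, grouping areas in cm^2 and gradient magnitudes keep their meaning.
Hemispheres land on disjoint half-planes, and gradient fits never mix
nodes across the midline.

The local phase gradient at a node is the vector $a$ maximising the
Gaussian-weighted mean resultant
$\big|\sum_i w_i e^{\,i(\theta'_i - a\cdot\Delta x_i)}\big|$ over
same-hemisphere neighbours, a circular-linear plane-wave regression that
is immune to phase wrapping. The "Gaussian window of size 20 mm" is
interpreted as a Gaussian weight with standard deviation 20 mm (the most
common convention; it is an exposed parameter). Because wrapping creates
local optima, the objective is first scanned on a coarse grid in gradient
space (half-width 0.25 rad/mm, which covers speeds down to the 1 m/s
floor at the frequencies considered) and then refined by BFGS with the
analytic gradient. Nodes with fewer than three effective neighbours, or
collinear ones (second-moment condition), are marked missing.

Propagation speed uses the contour identity $v = |d\theta/dt|/|\nabla
\theta'|$, with $d\theta/dt$ taken from the model's right-hand side at the
snapshot (`instRates`) — finite differences across 0.5 s epochs would
compare statistically independent states and are meaningless here.
Gradients below $10^{-4}$ rad/mm mark a near-synchronous patch: speed is
undefined there rather than spuriously large. The propagation direction
is $-\nabla\theta'$ for advancing phase (waves travel from phase-leading
to phase-lagging regions).

## Metrics

* **Order parameter** $R = |\frac1N \sum_j e^{i\theta_j}|$; **relative
  phase** $\theta'_j = \theta_j - \arg\sum_k e^{i\theta_k}$, wrapped to
  $(-\pi,\pi]$.
* **Segmentation.** Pairwise Cohen's d between parcels, per sample, with
  the pooled denominator divided by $N_i + N_j$ exactly as printed in the
  source formulation (not the usual $N_i+N_j-2$); a per-sample one-way
  ANOVA F; and a label-permutation test (2000 resamples) of each pair's
  time-averaged d with Benjamini-Hochberg FDR at 0.05. Relative phases
  are treated as linear quantities, which their centred, single-peaked
  sub-$\pi$ distribution justifies in the operating regime; the PCA entry
  point warns when the central 98% spread reaches $\pi$ in more than 5%
  of samples.
* **UCI.** $U_j = \frac1N\sum_k (0.5\cos(\theta_j - \theta_k -
  2\pi f_0 \tau_{jk}) + 0.5)$. The delay enters as the phase
  $2\pi f_0 \tau$ it subtends at the network's mean frequency — the
  dimensionally consistent reading of the printed $2\pi\tau/f_0$, which
  has units of s^2; the literal form stays available behind
  `literalDelayTerm = TRUE`. The **sequencing effect** is the per-sample
  OLS slope of $U_j$ on $f_j$, t-tested across samples.
* **SSI.** $S_j(r)$ averages $(x_k - x_j)\cdot g_k$ over an annulus
  (half-width default 10 mm, a value the source leaves unstated) using
  the outward-positive propagation-direction field $g = -\nabla\theta'$,
  so sources (phase cones) are positive and faster-centre epochs give
  larger SSI; the raw-gradient sign convention is a switch.
* **Grouping scan.** For circular areas (default 12 log-spaced values,
  10-400 cm^2) the OLS slope of pooled $\theta'$ on pooled $f$; the
  optimal area maximises |slope| and is undefined when no area shows any
  frequency dependence. The gradient-frequency regression uses the
  signed gradient component along the node's mean propagation direction
  (the source does not state which gradient functional enters; the
  signed-component reading is implemented and flagged), with a null built
  by shuffling whole epoch frequency vectors.

## Numerical choices

* **Integrator.** Forward Euler, default dt = 1 ms: the oscillation
  period at 10 Hz is 100 ms and delays of 1-30 ms are resolved; delays
  are rounded to integer steps and zero-weight pairs skipped. The delay
  history is a ring buffer; before t = 0 each node is extrapolated
  backward at its initial intrinsic rate, which avoids an artificial
  synchrony transient while staying deterministic. Frequency redraws are
  instantaneous at epoch boundaries. Euler preserves phase-locked fixed
  points exactly, which is what the closed-form tests exploit; a
  step-halving check is run on the locked attractor, because in the
  partially synchronised regime trajectories are sensitive to initial
  conditions and pointwise step-size comparisons over seconds are
  ill-posed for any explicit scheme. With conduction delays, the
  homogeneous-frequency network does not reach $R \to 1$: it settles
  into a periodic collective state with finite lags; complete synchrony
  under strong coupling is verified on the zero-delay network, where the
  classic result applies.
* **Randomness.** One root seed drives named substreams (connectome,
  schedule, initial phases, permutations); seeded runs are
  bit-reproducible.
* **Degenerate inputs.** Zero resultant (perfectly balanced phases) makes
  the relative phase undefined and errors; zero variance in intrinsic
  frequencies makes regression slopes undefined and errors; empty annuli,
  empty grouping disks and degenerate neighbourhoods yield missing values
  rather than numbers.
* **Problem sizes.** The package's reduced profile (N = 150 nodes, 21 s,
  40 retained epochs) reproduces every qualitative result of the
  full-scale configuration (N = 468, 101 s, 200 epochs) and is the
  default for tests and the acceptance script; the full profile is one
  flag away (`experimentConfig(profile = "full")`).

## A note on the homogeneous-frequency control

With $\sigma_f = 0$ every node has the same intrinsic frequency, so the
regression of UCI on intrinsic frequency is literally undefined (zero
variance in the regressor — `uciSlope()` errors, as it should). And for
any $\sigma_f > 0$ the slope is a per-Hz derivative, which does not
shrink as $\sigma_f \to 0$. The meaningful control is therefore a
null-label test: in the homogeneous run, UCI is regressed on exogenous
frequency labels drawn from the distribution the schedule would have
used. Those slopes must be statistically indistinguishable from zero —
and they are, while the heterogeneous run's slopes are significantly
positive.

## Known limitations

* Waves here are stable given the frequency schedule; empirical waves
  fluctuate spontaneously (cross-frequency interactions are out of
  scope, as are neural-mass dynamics and stochastic phase noise).
* The gyri-restricted surface map and sulcus/gyrus classification are
  not implemented; all analyses run on the full cortical map (in the real
  system both maps give near-identical speed statistics).
* Scalp-EEG forward modelling, tractography and template parcellation
  are out of scope; users with real connectome matrices can load them
  with `loadConnectome()` provided coordinates suitable for spherical
  projection.
* The contour-velocity identity $v = |d\theta/dt|/|\nabla\theta'|$ is the
  standard equivalent of tracking constant-phase contours; an explicit
  contour tracker could differ near map edges, which is why the test
  suite compares both on a ring geometry away from boundaries.
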