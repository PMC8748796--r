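# cortexwaves

Cortical oscillations do not synchronise as one block: on the cortical
surface, alpha/theta-band phases form *traveling waves*. If waves are
functional, they should do two things to the underlying regions — group
spatially contiguous regions into large-scale networks by phase
(*segmentation*), and order regions within the wave by their intrinsic
frequency so that, given conduction delays, communication becomes
directional from faster to slower regions
(*sequencing*, via communication-through-coherence). `cortexwaves` is an
R package for computational neuroscientists that simulates this mechanism
and quantifies both effects.

The dynamical core is a delay-coupled Kuramoto network on a spatially
embedded connectome,

$$\dot\theta_j = \omega_j(t) + \lambda \sum_k w_{jk}
\sin\big(\theta_k(t-\tau_{jk}) - \theta_j(t)\big),
\qquad \tau_{jk} = L_{jk}/v,$$

with intrinsic frequencies $f_j = \omega_j/2\pi \sim
\mathcal N(f_0, \sigma_f)$ redrawn every 0.5 s. On top of the simulated
phases the package computes: relative phases
$\theta'_j = \theta_j - \arg\sum_k e^{i\theta_k}$ and the order parameter
$R$; an equal-area (Lambert azimuthal) cortical map; local phase
gradients by Gaussian-windowed circular-linear regression and wave speeds
$v = |d\theta/dt| / |\nabla\theta'|$; phase-based network segmentation
(pairwise Cohen's d with label-permutation + FDR inference, ANOVA F);
relative-phase PCA; the unidirectional communication index
$U_j = \frac1N\sum_k\big(0.5\cos(\theta_j-\theta_k-2\pi f_0\tau_{jk})
+0.5\big)$ and its slope on intrinsic frequency (the sequencing effect);
the source-sink index for local radial waves (phase cones) and its slope
versus frequency and node degree; grouping-size scans; and parameter
sweeps over coupling, frequency spread and mean frequency.

A synthetic-connectome generator (nodes on two hemispheric caps,
distance-decaying weights with hubs, tortuous tract lengths, conduction
delays, seven contiguous bilateral network parcels) provides
statistically realistic inputs; real connectome matrices load from
delimited text via `loadConnectome()`.

## Worked example

```r
library(cortexwaves)

net  <- generateConnectome(syntheticConfig(nNodes = 150, seed = 1))
traj <- simulateNetwork(net, simulationConfig(tTotal = 21, seed = 1))
map  <- projectSurface(net)
field <- waveField(map, traj)
field
#> WaveField: 40 samples x 150 nodes
#>   speed: median 5.78 m/s (IQR 3.49-9.58), 5999 valid estimates

seqEff <- sequencingEffect(traj, net)
#> mean UCI slope = 0.079 (t = 9.8, p = 4.2e-12)

seg <- segmentation(traj, networkLabels(net), nPerm = 2000, seed = 1)
#> mean pairwise d = 0.80 (shuffled-label 95th pct = 0.34);
#> 15 of 21 pairs FDR-significant
```

Reading the numbers: the median wave speed (5.8 m/s) sits inside the
1–10 m/s axonal-conduction window, so the simulated waves propagate at a
biologically plausible rate. The positive UCI slope (+0.079 per Hz,
p ≈ 4e-12 across 40 epochs) is the sequencing effect: regions whose
intrinsic frequency is momentarily higher occupy earlier wave phases, the
configuration that favours outward communication. The mean pairwise
Cohen's d of 0.80 — far above the label-shuffled 95th percentile of
0.34 — is the segmentation effect: the seven network parcels occupy
distinct phase bands of the wave.

`runExperiment()` wires these stages together (with tables, summary JSON
and a run manifest), and `runSweep()` scans coupling strength,
$\sigma_f/f_0$ and $f_0$ to expose the segmentation–sequencing trade-off
and its frequency-band dependence.

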