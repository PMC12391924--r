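---
title: "megsi: models, simulator, solvers, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{megsi: models, simulator, solvers, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(megsi)
```

`megsi` is a self-contained sandbox for magnetoencephalographic (MEG)
source imaging: a physical forward model, a generator of ground-truth
brain activity and noisy sensor recordings, a windowed neural-network
inverse solver trained on those simulations, four classical inverse
solvers, and the localization metrics to compare them. This vignette is
the package's account of the science: the models and their assumptions,
the parameters that matter, what the simulator does and does not emulate,
and the design decisions taken where more than one defensible choice
existed.

## 1. The forward model

### Physics and assumptions

The conductor is a sphere, and the sensors are radial magnetometers. In a
spherically symmetric conductor the volume currents contribute nothing to
the radial component of the external magnetic field, so the radial reading
of a sensor at position $\mathbf{r}$ produced by a unit current dipole at
$\mathbf{r}_q$ with orientation $\Theta$ has the closed form

$$L(\mathbf{r}, \mathbf{r}_q, \Theta) \;=\; \frac{\mu_0}{4\pi}\,
\frac{(\mathbf{r}\times\mathbf{r}_q)\cdot\Theta}
     {r\,\lVert \mathbf{r}-\mathbf{r}_q\rVert^{3}},
\qquad r = \lVert\mathbf{r}\rVert,$$

with $\mu_0 = 4\pi\times10^{-7}$ H/m and SI units throughout (meters,
tesla, A·m). Two structural facts follow directly and are asserted as
tests: a *radial* dipole ($\Theta \parallel \mathbf{r}_q$) is silent, and
dilating all positions by $k$ scales every entry by $1/k^2$. The entry
equals the radial component of the free-space (Biot–Savart) dipole field,
which the test suite evaluates independently and compares at $10^{-10}$
relative tolerance.

This spherical closed form replaces the MRI-derived single-shell geometry
a subject-specific study would use. That is a deliberate trade: no
external data, exact physics, and every property checkable — at the cost
of realistic cortical geometry (see §7).

### Geometry defaults

* **Helmet**: `buildSensorHelmet(n, radius = 0.12, capFraction = 0.6)` —
  a Fibonacci spiral on the upper spherical cap covering 60% of the sphere
  at 12 cm, approximating a whole-head SQUID helmet. Orientations are
  radial by construction.
* **Source lattice**: `buildSourceGrid(radius, spacing = 0.005)` — the
  cubic lattice of the given step strictly inside the source sphere. Each
  dipole gets a fixed unit *tangential* orientation, drawn once from a
  seeded RNG: radial moments are provably silent here, so tangential
  orientations carry all measurable signal, folded into the leadfield so
  every solver works with one scalar amplitude per dipole. If the origin
  lattice point falls inside the sphere it is retained (the lattice
  examples require it) with a fixed $+x$ orientation and flagged — it is
  magnetically silent, and the scenario generator never selects it as a
  focal source or region seed.

## 2. The signal model

Each active source emits a Gaussian-damped sinusoid

$$g(t) = \sin(2\pi f_0 t + \phi)\,
         \exp\!\left[-\frac{(t-t_0)^2}{\omega^2}\right]$$

with parameters drawn independently and uniformly per activation:
$t_0 \in [0.05, 0.3]$ s (envelope center), $\omega \in [0.04, 0.12]$ s
(envelope width), $f_0 \in [8, 14]$ Hz (the alpha band), $\phi \in
[0, 2\pi)$ rad. Trials last 0.4 s at 1 kHz — 400 samples. All ranges are
configurable; no band-specific logic exists beyond the default range.

Activations are **focal** — 1–3 individual dipoles, each with its own
$g(t)$ — or **extended** — connected sub-volumes sharing a single $g(t)$.
Extended regions grow from a random seed voxel by uniform random frontier
accretion on the 6-neighborhood lattice, which yields compact, irregular,
connected blobs. Their target size is drawn as an integer voxel count
uniform on $[\lceil 14/v\rceil, \lfloor 44/v\rfloor]$ ($v$ = voxel volume
in cm³) rather than by rounding a continuous volume draw: on coarse desk
lattices rounding could step outside the 14–44 cm³ bound that the
benchmark asserts, while the integer draw respects it by construction.

Sensor noise is i.i.d. zero-mean Gaussian per sensor and sample. The SNR
convention (the literature rarely states one) is a **global power ratio**:
the noise variance satisfies
$\mathrm{SNR_{dB}} = 10\log_{10}\!\big(\overline{M_{\mathrm{clean}}^2} /
\sigma^2\big)$ with the clean power averaged over all sensors and samples.
This is the simplest convention consistent with "white noise added in
sensor space"; recordings store their clean part so the realized SNR can
always be audited (`realizedSnr`), and tests require agreement within
0.5 dB.

## 3. The windowed network

### Architecture

The network maps an $S \times W$ sensor window to the $D$ dipole
amplitudes at the window center ($W = 21$ samples by default — one period
of 50 Hz at 1 kHz). Sliding the window over a recording recovers the full
source time courses; the $(W-1)/2$ edge columns at each end are zero-filled
and flagged rather than fabricated from padding.

* **Temporal block**: four 1-D convolutions with feature schedule
  16–32–64–128, weights shared across sensors (each sensor is an
  independent instance of the same temporal filter bank), batch
  normalization between consecutive conv layers, ReLU after each. The
  kernel schedule must consume the window exactly to temporal extent 1;
  the default `c(5, 5, 3, 11)` realizes 21 → 17 → 13 → 11 → 1 with a
  full-width final kernel. The temporal/spatial division of labor is
  structural: no spatial mixing happens before the flatten.
* **Spatial block**: the flattened $S \times 128$ feature map feeds 6
  fully-connected ReLU layers of width 500, then a final linear layer with
  $D$ outputs.

The kernel sizes, conv activations, and normalization placement are this
package's choices; the feature schedule, layer counts, FC width, and the
"S vectors × 128 features" interface are the reference design. All are
configurable through `networkConfig`, which rejects any kernel schedule
that cannot collapse the window and reports the achievable extents.

### Training

Adam (learning rate $10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$) on
mean-squared error over minibatches of 64, implemented from scratch in
vectorized base R (BLAS-backed matrix algebra); training is fully
deterministic given the seed. Inputs are standardized per sensor and
targets scaled to unit maximum absolute amplitude — raw tesla magnitudes
(~fT) are numerically hostile to MSE training — with the constants stored
in the model and applied at inference (batch-norm uses running statistics
there, so predictions are batch-size invariant). A 10% validation split is
held out by default; early stopping is not used. Source amplitudes are
unit-peak per activation: absolute dipole moments are never stated in the
problem, and all benchmark metrics (DLE, AV, IoU, envelope NRMSE) are
scale-free.

### Desk-scale sizing

The reference design trains on $2\times10^5$ examples for ~30 h on a GPU.
This package's test suite exercises the same pipeline at desk scale: 32
sensors, a 25 mm lattice ($D = 81$) inside a 7 cm source sphere, 5000
training examples (even focal/extended split, SNR uniform on 0–30 dB), FC
width 250, 8 epochs — about ten minutes of CPU. At that scale the held-out
single-focal median DLE at 30 dB is within one lattice step, and the mean
DLE *improves* slightly from 30 dB to 10 dB — the network, trained across
0–30 dB, is noise-robust in exactly the way the full-scale design reports.
These sizes are stated here as the package's chosen study conditions; the
configuration accepts full-scale values unchanged.

## 4. Classical solvers

All four consume the same `Leadfield`/`SensorRecording` objects as the
network, so comparisons are apples-to-apples. All are scalar-per-dipole
(orientations folded into the leadfield), deterministic, and
config-exposed.

* **LCMV** beamformer: per dipole, $w = C^{-1}l / (l^\top C^{-1}l)$ —
  minimum output variance under the unit-gain constraint $w^\top l = 1$
  (asserted at $10^{-8}$; cross-checked against a KKT solve of the
  constrained quadratic program). Covariance: sample estimator over time
  with mean removal plus diagonal loading of 5% of the mean sensor
  variance by default. Silent (zero) leadfield columns get zero output and
  a flag rather than an undefined filter.
* **MNE**: $\hat{Q} = L^\top (LL^\top + \lambda I)^{-1} M$. Default
  $\lambda = 0.05\,\mathrm{tr}(LL^\top)/S$. The known-simulation-SNR
  discrepancy principle was considered and not used: the benchmark
  deliberately never leaks the true noise level to solvers. Tests pin the
  shrinkage limit ($\lambda \to \infty \Rightarrow \hat Q \to 0$), the
  interpolation limit (square invertible case at $\lambda = 0$), and
  agreement with the pseudoinverse at tiny $\lambda$.
* **eLORETA**: diagonal depth weights from the fixed point
  $w_i \leftarrow \sqrt{l_i^\top (L W^{-1} L^\top + \alpha H)^{+} l_i}$,
  iterated to a $10^{-6}$ relative change (cap 100 iterations, warning
  flag on non-convergence), then
  $\hat{Q} = W^{-1} L^\top (L W^{-1} L^\top + \alpha H)^{+} M$. $H$ is the
  identity (average-reference centering is an EEG concern);
  $\alpha = 0.05\,\mathrm{tr}(LL^\top)/S$ by default. The defining
  property — exact localization of noiseless grid-aligned point sources at
  any depth — is asserted directly.
* **RV scan**: per-dipole least squares $q_i = l_i^\top M / l_i^\top l_i$
  scored by the unexplained power fraction
  $\lVert M - l_i q_i\rVert_F^2 / \lVert M\rVert_F^2 \in [0, 1]$.

Numerical choices: pseudoinverses via symmetric eigendecomposition with
relative truncation at $10^{-12}$; covariance symmetrized after loading;
eLORETA weight floor for silent columns (the weight of a zero column is
replaced by the smallest positive weight so $W^{-1}$ stays finite — the
corresponding amplitude row is zero regardless).

## 5. Metrics

Activity is thresholded on **time-integrated energy** (sum of squared
amplitude over the valid samples): a dipole is active if its energy
exceeds 50% of the maximum. Instantaneous energy was the alternative; one
active set per trial is reported, which implies a time-integrated
criterion.

* **DLE** (mm): mean over true active sources of the minimum distance to
  any estimated active source. Computed between physical positions — no
  voxel snapping — so forward and inverse lattices may differ. Not
  symmetric (it averages over the first argument). An empty estimate
  yields `Inf` with a flag, and benchmark aggregation excludes such cases
  with a count rather than silently dropping them.
* **AV** (cm³): active voxel count × voxel volume.
* **NRMSE**: both traces normalized by the square root of their energy;
  envelopes via the magnitude of the analytic signal (FFT Hilbert
  transform — computed directly, as no installed package provides it);
  RMS difference of the envelopes. Scale-invariant by construction. An
  independent rectification + low-pass envelope cross-checks it at 5%.
  When truth and estimate live on different lattices, each true source is
  paired with the nearest active estimated dipole's trace.
* **IoU** (%): intersection over union of active index sets; when the
  estimate's lattice differs from the truth's, true positions are mapped
  to their nearest estimate-lattice voxel first.
* **Depth split**: the *deep point* is the dipole with the greatest mean
  distance to the sensors. Note a geometric subtlety: for an interior
  point at radius $r$ and a full sensor sphere of radius $R$ the mean
  distance is $R + r^2/(3R)$ — maximized at the *surface*, not the center.
  With the default upper-cap helmet the deep point sits at the bottom of
  the source sphere, which is what "deep" means under a helmet. Cases are
  ranked by distance to the deep point; the closest half form the deep
  subset.

## 6. The benchmark orchestrator

`runBenchmark(config)` reproduces the simulated study design at
configurable scale: for each scenario kind it draws seeded ground-truth
trials on the forward lattice, re-noises the *same* clean trials at every
test SNR (paired comparisons — the alternative, fresh trials per SNR, adds
between-condition variance for no benefit), runs every requested solver,
and aggregates mean ± sd per method × kind × SNR into CSV tables, with
per-case results persisted for audit. Distinct forward (fine) and inverse
(coarse) lattices are supported — the network reconstructs on the inverse
lattice, classical solvers on the forward one — though the desk-scale
default uses one 25 mm lattice for speed. Solvers never see ground-truth
activity; the only shared object is the forward operator itself, which is
the usual simulation caveat. Every run is replayable from its logged
configuration and seed.

Persistence is deliberately boring: geometry as TSV, configurations as
YAML, scenario descriptions as JSON, arrays as raw little-endian doubles
with a JSON manifest carrying shapes and MD5 content hashes (bit-exact
round trips, tamper detection), models as a directory bundle of
architecture JSON + weight arrays + scaler constants + loss history.

## 7. What the simulator does not emulate, and known limitations

* **Head geometry**: a sphere, not a cortex. No MRI segmentation, no BEM,
  no multi-shell conductivity. Consequences observed in this package's own
  experiments: classical solvers are somewhat *better*-behaved here than
  on realistic heads — notably, eLORETA's 50%-threshold localization
  remains exact down to ~10 dB in this geometry and only breaks below
  ~5 dB, whereas full-scale studies on MRI-derived heads report it
  collapsing already at 10 dB. Passing desk-scale tests therefore shows
  the machinery is correct, not that realistic-head performance numbers
  transfer.
* **Noise**: white and Gaussian only — no physiological artifacts, no
  correlated sensor noise, no brain-noise dipoles.
* **Sensors**: radial magnetometers only; no gradiometers, no free
  orientations.
* **Dipole orientations**: fixed tangential, chosen pseudo-randomly per
  lattice point. Real cortical orientations follow anatomy; nothing here
  models that.
* **Scale**: the network's capacity and training length default to
  desk-scale sizes; the configuration accepts full-scale values but the
  package makes no promise about wall time there.
* **Amplitudes**: unit-peak per activation; the network predicts in those
  units. Absolute moment calibration is out of scope, and all metrics are
  scale-free.

## 8. Reproducibility

Every stochastic step is seeded: lattice orientations
(`orientationSeed`), noise draws (recorded per recording), dataset
generation (one seed reproduces the entire set), training (initialization
and shuffling), and the benchmark (one seed replays everything).
`scripts/acceptance.R --seed N --out f.json` regenerates the headline
eLORETA localization quantity from a fresh geometry each run; the test
suite asserts the same properties under fixed seeds.
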