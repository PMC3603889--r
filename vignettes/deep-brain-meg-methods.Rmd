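---
title: "Assessing deep-brain MEG source localization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing deep-brain MEG source localization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbameg)
```

## The problem

Magnetoencephalography is most sensitive to superficial, tangentially
oriented cortical currents. Whether generators in the hippocampus,
amygdala, thalamus or basal ganglia are detectable at all — and how well
the standard linear inverse operators localize them — is a quantitative
question that depends on the interplay of source depth, cytoarchitecture
(open- versus closed-field cell populations), current density, and the
operator's depth-bias corrections. `dbameg` provides a fully synthetic,
self-contained testbed for that question: a structured source model with
per-structure dipole moment densities and orientation rules, a spherical
forward model, the wMNE/dSPM/sLORETA inverse family, resolution
(PSF/CTF) analysis, Monte Carlo localization-error experiments, and an
alpha-band eyes-open/eyes-closed contrast.

Everything is generated in code; no subject data is used or required.
That makes every result exactly reproducible from a seed, at the price
of simplified geometry — the closing section lists what the synthetic
anatomy does and does not emulate.

## The source model

`default_structure_specs()` defines five structures inside a spherical
conductor of radius 0.09 m:

| structure   | geometry                | extent  | DMD            | orientations |
|-------------|-------------------------|---------|----------------|--------------|
| cortex      | folded spherical-cap sheet | 750 cm^2 | 0.25 nAm/mm^2 | surface normals |
| hippocampus | curved tube surface     | 15 cm^2 | 0.4 nAm/mm^2   | surface normals |
| amygdala    | ellipsoid voxel grid    | 1 cm^3  | 1 nAm/0.01 cm^3 | random |
| thalamus    | ellipsoid voxel grid    | 8 cm^3  | 0.025 nAm/0.01 cm^3 | random |
| putamen     | ellipsoid voxel grid    | 9 cm^3  | 0.25 nAm/0.01 cm^3 | random |

The dipole moment density (DMD) is the net current moment per unit of
tissue; for the volume structures it is expressed per 0.01 cm^3 so that
for every structure the total current of a patch of extent $s$ is

$$Q = \mathrm{DMD} \times s \times 100 \;\text{nAm},$$

with $s$ in cm^2 or cm^3. A 1 cm^2 hippocampal patch therefore carries
40 nAm, a 1 cm^3 thalamic patch 2.5 nAm, rising linearly with patch
size. Per dipole, $q_i = \mathrm{DMD}\cdot A_i$ (surfaces, areas in
mm^2) or $q_i = \mathrm{DMD}\cdot V_i/10$ (volumes, mm^3).

Closed-field populations (thalamus, putamen) and the unoriented
pyramidal population of the amygdala receive seeded uniformly random
unit orientations (normalised Gaussian triples); sheets use outward
vertex normals; a `principal_axis` rule (dominant eigenvector of the
envelope's position covariance) is available for small oriented nuclei
such as LGN/EGP/RPN analogs, which are supported but not part of the
default anatomy.

### Geometric choices

The cortex analog is a spherical cap (polar angle 0.15–2.0 rad) whose
radius is modulated by azimuthal ridges, $r(\theta,\phi) = r_0\,[1 +
0.12\,\sin(9\phi)\sin(10(\theta-\theta_0))]$, emulating gyral folding:
the ridges tilt the surface normals tangentially, which is what gives a
real cortex most of its MEG visibility. After meshing, the sheet is
rescaled radially about the conductor centre so its total area is
exactly 750 cm^2; with the folding this places it at radii 0.066–0.088 m.
The hippocampus analog is a tube of 4 mm radius swept along a
great-circle arc at 0.058 m (about 65% of the conductor radius), scaled
about its centroid to exactly 15 cm^2. Volume nuclei are 2 mm regular
grids (6-connectivity); the grid keeps exactly the $n$ voxels closest to
the centre in the ellipsoid norm, so the realised volume matches the
target to the voxel. The nuclei are placed within about 2 cm of the
conductor centre and checked pairwise for overlap.

Sensors are 151 radial magnetometers on a Fibonacci spiral covering the
upper 45% of a sphere of radius **0.10 m**. We initially used a 0.11 m
shell, but a 2 cm standoff between conductor surface and sensors is
larger than the scalp–dewar gap of real whole-head systems and
compresses the dynamic range between superficial and deep sources below
what is physically observed; at a 1 cm standoff the median cortical
sensitivity exceeds the pooled deep-nuclei median more than tenfold,
reproducing the order-of-magnitude separation expected of real
recordings. This tenfold separation was fixed as a property of the
default geometry before any localization experiments were run.

### What the "seven subjects" become

Group variability is emulated by seeds: the anatomy builder accepts a
`jitter` amplitude (relative radial vertex perturbation) and a seed that
also drives the random orientations, and the Monte Carlo driver sweeps
seven noise seeds by default, each standing in for one subject's
background activity.

## Forward model

The lead field uses the analytic solution for a current dipole in a
homogeneous conducting sphere (Sarvas formula), projected onto each
sensor's orientation. For exactly radial magnetometers this equals the
free-space dipole term, because volume currents contribute no radial
field in spherical symmetry — the tests exploit this as an independent
closed-form oracle. Radial dipoles and dipoles at the centre are exactly
silent, so the cortical sheet's folding (not its area) controls its
sensor coupling. Units are SI throughout (positions m, moments A·m,
fields T); the nAm currents of the source model are converted at the
interface.

## Inverse operators

All three operators derive from the depth-weighted minimum-norm kernel

$$K = S G^{t} (G S G^{t} + \lambda^2 C)^{-1}, \qquad
\lambda^2 = \frac{\mathrm{tr}(G S G^{t})}{\mathrm{tr}(C)\,\mathrm{SNR}^2},$$

with $C$ the sensor noise covariance (estimated from a 200 ms baseline
with 5% diagonal loading — 250 samples against 151 channels is
ill-conditioned without it), $\mathrm{SNR}=3$ the regularization
parameter, and $S_{ii} = \lVert G_i \rVert_F^{-2w}$ the depth-weighting
source covariance computed from the three-column free-orientation gain
($w = 0.6$ by default; $w = 0$ gives the classical MNE).

* **dSPM** divides row $i$ of $K$ by $\sqrt{(K C K^t)_{ii}}$, so pure
  noise drawn from $C$ yields unit-variance source estimates.
* **sLORETA** divides row $i$ by $\sqrt{(KG)_{ii}\,S_{ii}}$, the model
  standard deviation of the estimate,
  $\mathrm{diag}(K(GSG^t+\lambda^2C)K^t)$. For $S = I$ this is the
  classical division by $\sqrt{R_{ii}}$ with $R = KG$; the extra
  $\sqrt{S_{ii}}$ factor is required for the exact zero localization
  error of noiseless point sources to survive depth weighting. Writing
  $R' = S^{-1/2} R S^{1/2}$, which is symmetric positive semidefinite,
  the standardized point-source response is $R'_{ij}/\sqrt{R'_{ii}}$ up
  to a factor constant in $i$, and the Cauchy–Schwarz inequality puts
  its maximum at $i = j$. The test suite verifies zero error at every
  source of a 2000+ source anatomy.

Because both normalizations only rescale rows of $K$, the rows of the
resolution matrix $R = KG$ (the cross-talk functions) keep exactly the
same shape across the three operators, while its columns (point-spread
functions) differ — the suite asserts both identities to machine
precision.

## Simulation design

Activation patches grow from a seed dipole by a distance-ordered
breadth-first search over the structure's adjacency graph (mesh edges or
6-connected voxels), ties broken by index for determinism, until the
cumulative element size reaches the target (1–5 cm^2/cm^3; structures
smaller than the target are used whole, with a warning). Each patch is
modulated by a unit-peak Gaussian envelope of 30 ms FWHM after a 200 ms
silent baseline, at 1250 Hz. When a cortical co-activation (3 cm^2, at a
posterior "visual" seed) is present, its peak precedes the subcortical
peak by $D_t \in [0, 60]$ ms; the realized cortical amplitude ratio at
the subcortical peak is $R_c = \exp(-4\ln 2\,(D_t/\mathrm{FWHM})^2)$
(100% at $D_t = 0$, 50% at 15 ms, effectively 0 at 60 ms).

The summed noiseless field is rescaled so that its total energy is
exactly `snr_energy` (default 20) times the energy of the added noise
segment — the evoked-average regime. The surrogate background noise is
synthesized in the frequency domain: independent $1/f$ channels plus a
shared narrowband 10 Hz component added with random signs and scaled so
the PSD bump at the alpha peak is a configured multiple of the
background there.

Localization is evaluated at the subcortical peak sample with two
errors, both in cm against the patch seed (a `truth = "centroid"` switch
uses the current-weighted patch centroid instead): `dle_g`, the distance
from the gravity centre of the estimate thresholded at 50% of its
maximum (the threshold is global, over the whole source space), and
`dle_m`, the distance from the estimate's maximum, ties to the lowest
index. Detection around a deep truth uses the largest
adjacency-local-maximum above the global 50% threshold within a 4 cm
ball.

## Monte Carlo driver and problem sizes

`run_grid()` sweeps structures x seed sources x patch sizes x $D_t$ x
noise seeds x operators, rebuilding the noise covariance and kernels per
noise seed, and records both DLEs (plus detection for two-source cells);
failed cells are recorded, never dropped. Aggregation produces per-source
means across noise seeds, unit-mass DLE histograms per condition, and
detection-rate-versus-$R_c$ curves.

The package's own test and acceptance runs use reduced problem sizes
chosen to keep every property at full strength while remaining quick to
recompute: a ~1300-source anatomy (mesh resolution 0.5, 4 mm grids) for
kernel work, the full ~6300-source anatomy for the sensitivity ordering,
a >2000-source anatomy for the sLORETA zero-error sweep, three noise
seeds and every fourth hippocampal seed for the reported Monte Carlo
summary, and 5 s blocks at 250 Hz (8 per condition) for the
eyes-open/eyes-closed experiment. All sizes are parameters, so
full-density runs are one argument away.

## Eyes-open / eyes-closed contrast

`synthesize_eo_ec()` places narrowband 10 Hz generators at thalamic and
posterior-cortical dipoles, projects them through the gain on top of
independent $1/f$ sensor noise, and multiplies the source amplitudes by
`modulation_ratio` in the eyes-closed condition. `alpha_contrast()`
band-passes each block (Butterworth applied forward–backward, corner
frequencies placed at a geometric margin outside the 8–12 Hz band so
the in-band ripple stays under 1 dB), projects to sources through an
inverse kernel, computes per-block band power, contrasts conditions with
a two-sample Student t-test across blocks, and controls FDR with
Benjamini–Hochberg at 0.05. Blocks are the test unit: with the
synthetic block design they are exchangeable under the null, which the
calibration test verifies empirically over 20 seeds; recovery of at
least one truly modulated thalamic source at ratio 3 is likewise checked
over 20 seeds.

## Numerical and design notes

* The SNR is energy-based and reads activation/noise = 20; the
  convention direction is stated here because "ratio" alone is
  ambiguous.
* $R_c$ is an amplitude (envelope) ratio, not an energy ratio.
* Degenerate inputs error early: sources on/outside the conductor,
  silent patches with a nonzero SNR target, all-zero estimates in the
  DLE metrics, non-positive sLORETA diagonals (naming the source).
* Silent-source depth weights are capped with a warning rather than
  propagating infinities; the default anatomy has no exactly silent
  source (nucleus grids are deliberately not aligned with the conductor
  centre, where a dipole would be magnetically invisible).
* Coarse meshes cannot both resolve the cortical folds and hold the
  750 cm^2 area inside the conductor; mesh resolutions below about 0.4
  are therefore rejected by the geometry checks rather than silently
  producing an unfolded sheet.
* Averaged structure maps normalize each per-source map to unit maximum
  before pooling, then renormalize, so every source contributes equally
  regardless of its absolute resolution-matrix scale.

## Limitations

The synthetic anatomy reproduces the *regime* of deep-source MEG —
depth ordering, orientation statistics, per-structure current budgets,
sensitivity separation — not any individual's geometry: there are no
real sulcal patterns, no inter-hemispheric asymmetry, no CSF/skull
layers (a single-sphere conductor), and radial magnetometers rather
than gradiometers. Published group-level error maps depend on real
anatomies and real resting noise, so passing this package's checks
shows the operators and metrics behave correctly under the stated
model, not that any particular error value transfers to a given
subject. The spherical model also makes radial sources exactly silent,
which is only approximately true in realistic head models.
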