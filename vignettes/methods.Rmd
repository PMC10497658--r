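---
title: "Models and methods: CSF flow impedance and tissue-motion decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: CSF flow impedance and tissue-motion decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models, their
assumptions, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices behind the
implementation. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The problem

In Chiari malformation type I (CMI) the cerebellar tonsils crowd the
craniocervical junction, narrowing the spinal subarachnoid space (SAS)
through which cerebrospinal fluid (CSF) pulsates with every heartbeat. Two
biomechanical consequences can be quantified independently: the *unsteady
resistance* the cervical canal presents to oscillatory CSF flow, summarised
as the integrated longitudinal impedance (ILI), and the *cardiac-induced
displacement* of the cerebellum and brainstem, measured by DENSE MRI, which
encodes tissue displacement directly into image phase. This package
implements both measurement chains at desk scale, plus the cohort statistics
linking them, with seeded synthetic data standing in for subject scans
(which the study design assumes but does not deposit).

## Unsteady resistance: the oscillatory duct-flow surrogate

### Model

The original workflow solved transient 3D Navier-Stokes on subject-specific
meshes. Here the canal is treated slice by slice: on each cross-section
$\Omega(z)$ the axial velocity $u$ of the harmonic at angular frequency
$\omega$ satisfies the fully developed oscillatory (Womersley-type) flow
equation

$$ i\omega\rho\, u = G + \mu \nabla^2 u, \qquad u|_{\partial\Omega} = 0, $$

with $G = -\partial p/\partial z$ spatially uniform on the slice. The
complex *mobility* $M(z,\omega)$ is the volumetric flow per unit pressure
gradient, $Q/G$; the longitudinal impedance of a segment is the series line
integral

$$ Z_L(\omega) = \int_{z_0}^{z_1} \frac{dz}{M(z,\omega)}, $$

which is by construction additive over contiguous segments and — because the
model is linear — independent of the shape or amplitude of the driving
waveform. ILI is the trapezoidal integral of $|Z_L(f)|$ over 1–8 Hz,
evaluated on a uniform grid of 29 frequencies; its units,
dyn·s/cm⁵ × Hz = dyn/cm⁵, match the reported quantity, which is why the
band *integral* (not a sum over discrete harmonics) and the *modulus* (not
the real part) are the defaults. Both alternatives are exposed
(`compute_ili(reduction=, quadrature=)`), since the field literature states
the reduction loosely.

Assumptions inherited from this surrogate: fully developed flow (no
entrance or advective effects — the regime the original meshes were extended
precisely to reach), rigid walls (the original simulations were also static;
moving-wall studies report ILI magnitudes roughly a fifth larger, so
absolute ILI here is systematically conservative for large-motion subjects),
Newtonian CSF with density 1.0 g/cm³ and viscosity 0.01 poise (water at body
temperature). All hydrodynamics are computed in CGS units; raster spacing
and axial positions enter in mm and are converted at the boundary.

An equivalent time-domain route is provided for parity with pressure/flow
traces: `reconstruct_pressure_trace()` synthesises $\Delta P(t)$ from the
waveform's Fourier coefficients, and
`longitudinal_impedance_from_traces()` recovers $Z_L$ as the ratio of
Fourier coefficients, dropping harmonics whose flow coefficient falls below
$10^{-8}$ of the largest rather than dividing by them. The original
workflow's three-cycle startup convention is unnecessary in this linear
frequency-domain setting and is retained only as a documented difference.

### Discretisation

The Helmholtz problem is discretised with central differences on the mask
raster and solved as a sparse real block system (one LU per frequency,
deterministic ordering, bit-reproducible for a fixed grid). A plain 5-point
stencil with walls at outside pixel centres converges only first order in
the staircase boundary, so boundary-adjacent links use Shortley–Weller
sub-pixel wall distances: exact distances when the section carries a signed
distance field (every generated section does), and half-pixel distances for
purely binary masks. With the distance field the scheme shows
second-order convergence against the closed-form Womersley pipe solution;
the binary fallback stays well within the 2% oracle tolerance at ~32 pixels
per radius.

Hydraulic metrics use the same sub-pixel idea: area is the sum of
fractional pixel coverage (or the pixel count for binary masks), and the
wetted perimeter — inner (cord) and outer (dura) contours both count, since
both surfaces are walls — is the length of a marching-squares isocontour:
the zero level of the signed distance field when available, otherwise the
0.5 level of the binary mask pre-smoothed with a 1-pixel Gaussian (the raw
binary isocontour overestimates perimeter by ~5%, corrupting $D_H = 4A/P$).
The inlet peak Reynolds number `4 rho Q / (pi mu D_H)` is evaluated at
z = 0 by convention, with per-slice values available from the metrics
table, since the source material does not pin the station beyond "at the
inlet".

Degenerate inputs: empty masks, masks touching the raster frame, and
sections with fewer than 10 lumen pixels are rejected; disconnected
fragments under 10 pixels (segmentation debris) are dropped with a warning,
while several genuine components are retained — CSF can flow through
parallel channels, and all of them conduct.

## DENSE displacement decoding

Displacement is encoded linearly into phase at $k_e$ cycles/mm (default
0.6), so $u = \phi / (2\pi k_e)$; with two encoding directions
(anterior–posterior, cranial–caudal) the reported scalar is the Euclidean
norm of the two components. The chain is: boundary erosion of each region
mask (default 2 voxels, guarding against partial-volume contamination), 2D
quality-guided phase unwrapping per frame and region ("if needed": frames
without any neighbour jump beyond $\pi$ pass unchanged), decoding, spatial
noise filtering, and ROI summarisation.

Numerical choices worth stating:

* **Unwrapping** grows from the highest-quality seed (quality = negative
  local wrapped-gradient energy), offsetting each new pixel by the multiple
  of $2\pi$ matching its best unwrapped neighbour. Spatial unwrapping leaves
  a global $2\pi k$ ambiguity — the seed may itself sit inside a wrapped
  island — so each region is re-anchored so that its median phase lies in
  $(-\pi,\pi]$, the physically sensible branch when most of the region moves
  less than half an encoding wavelength.
* **Filtering** applies a Hamming windowed-sinc FIR kernel (normalized
  cutoff 0.15, order 16) separably along rows then columns with replicate
  edge padding, mirroring 2D filtering of displacement maps with a
  1D-designed kernel. The kernel is normalized to unit DC gain so uniform
  motion passes unchanged; the textbook `fir1(16, 0.15)` kernel has a DC
  gain of 1.154, which would scale every displacement by 15%. Filtering maps
  (not phases) follows the stated processing order of the measurement
  chain.
* **ROI summary**: per pixel the temporal peak of the displacement
  magnitude is found within the (eroded) region; a circular ROI of ~30 mm²
  (radius 3.09 mm) is centred on the argmax pixel, shifted minimally when it
  does not fit inside the region; the reported "displacement" is the
  temporal maximum of the ROI's *spatial mean* magnitude. The mean is the
  default because it is far less noise-sensitive than the within-ROI
  maximum; the wording of the field convention admits both readings, so the
  max is exposed via `statistic = "max"`.

## Synthetic-data generators

The generators define the study conditions; their defaults are fixed, not
tuning knobs.

**Canal geometry** (`make_geometry()`): an annular canal from the foramen
magnum to 60 mm caudal, rasterised with exact signed distance and coverage.
`crowding_factor` narrows the annular gap over the first 25 mm — full
narrowing held over the first 10 mm, recovering linearly by 25 mm
("plateau"; a purely linear recovery is available). The plateau profile is
what lets a rasterisable gap span the reported ILI range: with a strictly
linear recovery the narrow region is too short, and matching the upper ILI
range would require sub-pixel gaps.

**Flow waveform** (`make_waveform()`): a zero-mean truncated 4-harmonic
pulse with a systolic peak, 86.3 bpm and 100 samples per cycle by default
(step 6.95 ms), peak 2.5 cm³/s — a typical cervical CSF stroke. Shape seeds
perturb the harmonics for the waveform-invariance tests.

**DENSE phantom** (`make_dense_phantom()`): a 72×72 grid at 0.9 mm with a
cerebellum disc and brainstem ellipse, Gaussian-bump displacement fields
(default peaks 300/180 µm, σ = 12 mm) under a smooth periodic pulse
(20 frames at 34 ms), phase-encoded, wrapped, and corrupted with
complex-channel Gaussian noise at magnitude SNR 20. The 12 mm spatial scale
is deliberate: the FIR kernel spans ~2 mm, and tissue-scale cardiac motion —
what the reference cyclical-motion phantom mimics — varies over centimetres;
a field undersampled relative to the filter would measure the filter, not
the pipeline. What the phantom does *not* emulate: spiral k-space
acquisition, gating jitter, through-plane motion, susceptibility artefacts —
so passing phantom tests bounds decoding/processing error, not scanner
physics.

**Cohort** (`make_cohort()`): a latent crowding factor per subject drives
the geometry (hence ILI through the impedance module) and, in the coupled
mode, cerebellar displacement; brainstem displacement is independent noise
in every mode, so no brainstem correlation is ever induced. Crowding values
are assigned by drawing per-subject target ILIs from lognormals
moment-matched to the reported group statistics (485 ± 184 dyn/cm⁵ CMI,
244 ± 38 control) and inverting a crowding→ILI calibration curve computed
with the same pipeline settings — so coarse-raster discretisation bias
cancels and achieved moments track the targets; draws outside the
attainable range are clamped with a warning when frequent. The cohort
rasters are deliberately coarse (0.5 mm pixels, 4 slices, $Z_L$ solved at 9
frequencies and splined onto the 29-point band grid, interpolation error
~0.1%): these are the package's problem-size choices for batch work, and
the calibration construction makes the statistical structure independent of
them. The `"graded"` mode implements coupling strength that grows with
displacement: above the 45th latent percentile displacement lies exactly on
a line in ILI, below it a *downward-only* disturbance (motion dissipated,
e.g. by compliance variation) scatters subjects off the line. Downward-only
noise is essential: symmetric heteroscedastic noise lets low-crowding
outliers contaminate high-displacement subsets, and ordinary range
restriction then *weakens* subset correlations no matter how the noise is
graded.

Symptom flags (five, with the reported CMI frequencies), MPQ/DIQ scores and
one unassessed subject are attached for interface parity; they are
independent of the biomechanical measures by construction.

## Statistics

Group contrasts use Welch's unequal-variance t-test (two-sided, as
throughout; sidedness is not stated in the field convention but the
reported p-values are conventional two-sided scales), normality checks use
Shapiro–Wilk, and the ILI–displacement relationship uses Pearson r with its
t-distribution p-value plus OLS with a free intercept and 95% CIs. These
delegate to R's vetted routines (`t.test`, `shapiro.test`, `cor.test`,
`lm`); the tests cross-check Pearson against a brute-force
sums-of-products oracle. No multiple-testing correction is applied,
mirroring the analysis being reproduced; a Bonferroni adjustment can be
applied downstream if wanted. The cutoff subset analysis restricts the CMI
group to subjects with cerebellar displacement strictly greater than each
cutoff (150/200/250 µm; "minimum values of tissue motion" read as strict,
with ties at the cutoff counted and reported) and emits (cutoff, n, r, p),
marking subsets under 3 subjects not-computable.

## Problem sizes and reproducibility

Deterministic behaviour is part of the contract: every generator takes a
seed and restores the caller's RNG state; `run_pipeline()` is bit-identical
under a fixed `run_config()`, and every output table carries the config
hash. The test suite uses fixed seed sets for its stochastic properties.
Sizes used by the suite and scripts — 50 phantoms for the accuracy bound,
20 seeds per cohort mode, 48–64 pixels per radius for the solver-oracle
comparisons — were chosen as the package's own balance of statistical
resolution against desk-scale run time.

## Known limitations

* The surrogate omits entrance effects, advection, secondary flow and wall
  motion; ILI values are faithful to the fully developed rigid-wall model,
  not to transient 3D CFD, and the rigid-wall assumption biases ILI low for
  large-motion subjects.
* Binary masks without sub-pixel information fall back to half-pixel wall
  placement and smoothed-contour perimeters (first-order accurate;
  adequate at segmentation resolutions but below the generated-geometry
  fidelity).
* The phantom's noise model (complex Gaussian, uniform SNR) flattens the
  spatially varying noise of real reconstructions; the cohort generator's
  lognormal latent structure is a modelling bridge, not an estimate of any
  real population.
* Uniformly wrapped fields (every pixel beyond the encoding range, no
  spatial gradient) are unrecoverable in principle; the unwrapping anchor
  assumes most of each region moves within half an encoding wavelength.
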