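---
title: "Models and methods behind ysegdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ysegdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ysegdose)
```

`ysegdose` quantifies how the choice of tumor segmentation — anatomic
(morphologic segmentation, MS) versus emission-driven (gradient-based
PET segmentation, PS) — changes reported absorbed-dose (AD) and
biological-effective-dose (BED) metrics in ⁹⁰Y microsphere
radioembolization. Because real patient scans cannot ship with a ground
truth, every input here is simulated with a known truth, and the
package's claims are therefore claims about this simulation, validated
against the accuracy envelope expected of the gradient method on
physically realistic phantom geometry. This vignette records the
models, the tunable parameters and the design decisions, including the
ones that were genuinely open.

## The simulator

**Geometry.** A phantom (`phantom_spec()`) is an ellipsoidal liver of
nominal volume 1200 cm³ containing ellipsoidal lesions; everything is
rasterized by voxel-center inclusion on the PET grid, 4.07 × 4.07 × 3 mm
voxels. Voxel `(i, j, k)` maps to the physical center
`origin + (i−1, j−1, k−1)·spacing`, and all distances are between voxel
centers. Rasterization by center inclusion means mask volumes carry a
bias below one voxel shell; tests measure it rather than hide it.

**Activity.** The truth image is piecewise constant: background
concentration `c_b` in the liver, `TBR · c_b` in each lesion's perfused
region, zero outside and in necrotic cores. `c_b` is solved so the total
activity over the *voxelized* grid equals the specified total exactly
(e.g. 3.0 GBq; a 1200 cm³ lesion-free liver gives 2.5 MBq/mL). In a
cold-background phantom the background is zero and lesion activities
are apportioned by TBR weights.

**Resolution.** The reconstruction chain is emulated in image space by
an isotropic Gaussian point-spread function, FWHM 5 mm
(σ = FWHM/2.3548, separable convolution with zero padding). No
sinogram/OSEM simulation: the analysis operates on reconstructed
images, so image-space blur is the right level of abstraction for a
desk-scale study, but it does mean reconstruction-specific artifacts
(streaks, nonstationary resolution, positivity bias of OSEM at low
counts) are absent.

**Noise.** ⁹⁰Y PET noise level is not well characterized by a single
published number, so the model is a declared assumption: zero-mean
Gaussian noise with standard deviation proportional to
`sqrt(signal + floor)`, spatially correlated by a Gaussian of 1 voxel,
and scaled so the *realized* coefficient of variation in the warm liver
background hits the single exposed knob `background_cov`
(default 0.25). Two details matter:

* the blurred background already varies near edges, so the added-noise
  variance is the target variance minus that baseline variance —
  otherwise the realized CoV would systematically overshoot the knob;
* a cold phantom has no warm background, so the sphere plateau is used
  as the calibration region with the target scaled by `1/sqrt(5)`,
  giving the plateau the same relative noise as a TBR-5 lesion in a
  warm phantom.

Negatives are clipped to zero (as in magnitude-style reconstructions).
The noise is deterministic given the seed.

**Patient-like cohorts.** `make_patient_cohort()` draws 1–9 lesions per
patient with log-uniform volumes in 2–818 cm³, each randomly fully
perfused, partially perfused (perfused fraction in [0.3, 1), a planar
cut) or rim-type (necrotic core fraction 0.3–0.7). The MS mask is the
true shape displaced by a per-axis Gaussian translation (default
σ = 2 mm) emulating residual rigid registration error of an
anatomy-derived contour; the truth mask is undisplaced. TBRs are
log-uniform in [1.5, 6] and per-patient activity uniform in
[0.6, 4] GBq, chosen once so lesion mean ADs span roughly 14–650 Gy —
the clinically reported range this package aims to exercise, which
matters because BED is nonlinear in dose. Lesion placement is rejection
sampling inside the liver with a ≥ 1 voxel gap between lesions; volumes
that cannot be placed are redrawn smaller. What the cohort does *not*
model: respiratory motion, deformable misregistration, inter-lesion
concentration heterogeneity beyond the TBR draw, and real microsphere
clustering texture. Passing cohort tests therefore show the pipeline's
statistical machinery behaves correctly under clustered, heterogeneous,
misregistered inputs — not that the simulation reproduces any clinical
cohort's numbers.

## Gradient-based segmentation

The clinical tool this emulates is interactive and proprietary, so the
package defines its own concrete realization and validates it against
the accuracy envelope expected on phantoms:

1. smooth the image (Gaussian, `smooth_sigma` voxels);
2. cast `n_directions` near-uniform rays (subdivided icosahedron; 42,
   162 or 642 directions) from the seed;
3. sample the smoothed image along each ray (`step` mm) out to the
   octant-ellipsoid bound built from the six initialization rays ×
   `margin`;
4. smooth each sampled profile *along the ray* (`profile_sigma_mm`) and
   set the per-ray radius at the most negative outward derivative, with
   parabolic sub-step refinement;
5. regularize radii by `regularization_iters` passes of angular
   neighbor-median smoothing;
6. voxelize the star-convex surface by a center-inside test (radius
   interpolated between the three nearest directions);
7. re-derive seed and rays from the detected mask and repeat until the
   mask is a fixed point (`refine_iters` cap).

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `smooth_sigma` | 0.5 voxels | 1 voxel is 4.07 mm in-plane; on top of the 5-mm PSF that biases small-lesion volumes inward 20–27% through the curvature–blur interaction. 0.5 keeps noiseless recovery of ≥ 8 cm³ spheres within 5%. |
| `profile_sigma_mm` | 1.5 mm | 1D smoothing of a blurred step *along the ray* widens the transition without moving its inflection, so it suppresses correlated-noise dips at almost no localization cost; 2 mm begins to bias small spheres (−8%), 1.5 mm stays within the 5% envelope. |
| `n_directions` | 642 | angular spacing ≈ 8°, well under the angular scale of an 8 cm³ lesion. |
| `step` | 1 mm | sub-voxel sampling; must not exceed the smallest spacing. |
| `r_min` | one voxel diagonal | keeps the surface off the seed voxel; capped per direction at 55% of the search bound so 2 cm³ lesions keep a usable window. |
| `margin` | 1.3 | the true edge stays searchable when the operator under-draws the rays. |
| `regularization_iters` | 2 | median over ~6 angular neighbors, twice: robust to single-ray outliers while preserving ellipsoidal anisotropy. |
| `refine_iters` | 6 (cap) | see below; convergence is typically reached in 2–3 passes. |

**Why the fixed-point refinement exists.** The interactive tool's rays
snap to its own gradient-determined edge, so the *effective*
initialization an operator ends with is the tool's own estimate. The
package mirrors this: after voxelization, the seed and rays are
re-derived from the detected mask (seed on the voxel grid, rays
quantized to half-voxels) and the search repeats until the mask stops
changing. Because the re-derived initialization is quantized, two runs
started from slightly different operator inputs (e.g. a 2-mm jitter)
almost always converge to the *identical* mask — this is what makes the
repeat-segmentation Dice ≥ 0.99 achievable at realistic noise. A
refinement pass uses an additive escape band (two voxels) on top of the
multiplicative margin, so a badly under-drawn start cannot trap the
surface inside the true edge; a 2-cycle, if one occurs, is resolved to
its larger member so both phases agree; and a refinement pass that
finds no edges keeps the previous surface rather than failing.

**Degenerate inputs.** A flat image (no structure along ≥ 20% of rays)
is an error. Rays that merely lack a falling edge — e.g. rays from a
seed in a non-perfused lesion part, looking toward hotter tissue — are
filled from their angular neighbors instead; and if the MS-centroid
seed itself is stranded in cold tissue, the pipeline emulates the
clinical nudge of the starting point onto the uptake (hottest smoothed
voxel inside the MS) before giving up. Scale invariance holds by
construction: the derivative's *location* is unchanged by positive
rescaling.

**Threshold segmentation** (`threshold_segment()`) keeps the
26-connected supra-threshold component containing the in-bound maximum,
with the bound a sphere of the MS equivalent radius + 10 mm. It exists
to demonstrate the TBR dependence of percent-of-max thresholds: for a
blurred edge the half-rise sits at (plateau + background)/2, so the
volume-optimal percent is strictly higher against a warm background
than a cold one, and a cold-optimal percent overestimates warm-background
volumes. The package asserts the direction, not specific percents,
which are scanner- and noise-specific.

## Dosimetry

Local deposition: `D = (C/ρ) · Δ/λ`, with Δ = 0.9267 MeV per decay,
λ = ln 2/64.1 h = 0.0108 h⁻¹, ρ = 1.0 g/mL (water phantom; 1.06
available for soft tissue). Microspheres are permanently trapped, so
time integration is pure physical decay — activity divided by λ. This
is the standard desk approximation at PET resolution (≥ 5 mm blur
already exceeds the ⁹⁰Y beta range); full Monte Carlo transport is out
of scope, and `dose_kernel_convolve()` (an energy-conserving radial
kernel resampled to the grid, applied by FFT) exists to bound what
transport would change. Energy is conserved exactly under local
deposition and within 0.5% under the kernel.

## Metrics

* `Dq` = empirical quantile of the voxel-dose sample at probability
  `1 − q/100`, linear interpolation at plotting positions
  `(i−1)/(n−1)` (the interpolation rule was an open choice; this one is
  deterministic and continuous in q, and differences against nearest-bin
  rules are sub-voxel).
* BED per voxel, `BED = D + D²/(α/β) · λ/(λ+μ)` (α/β = 10 Gy,
  μ = 0.462 h⁻¹), then summarized. Applying the transform per voxel is
  the zero-bin-width limit of a differential-DVH computation and avoids
  a binning parameter; because the transform is monotone,
  `BEDq = bed_transform(Dq)` exactly.
* EUD/EUBED `= −(1/α) ln mean exp(−α·d)` with α = 0.004 Gy⁻¹. At these
  dose levels the exponential is nearly linear, so EUD tracks the mean
  closely — the package tests r > 0.95 on lesion-like samples.
* DSC `= 2|A∩B|/(|A|+|B|)`; two empty masks are defined to agree
  (with a warning) so batch runs stay total.
* MDA: boundary voxels are those with a 6-connected neighbor outside
  the mask (grid border counts as outside); the metric is the symmetric
  average of the two directed mean nearest-surface distances in mm.
  The directionality convention was open; the symmetric average is used
  and tested against an O(n²) brute-force oracle.

## Statistics

Lesions cluster within patients, so naive CIs are too narrow. The
package resamples *patients* with replacement (percentile bootstrap,
default 2000 replicates, deterministic given the seed) for mean
PS − MS differences and reports Pearson r alongside Lin's ccc
(population-moment, divide-by-n convention) — ccc penalizes bias
against the identity line, so |ccc| ≤ |r| always. A mixed-effects model
would be the textbook alternative for the mean-difference test; the
clustered bootstrap preserves the same protection against within-patient
correlation without an REML dependency, and its CI calibration is
verified by a coverage simulation (200 replicates of a known clustered
design, 95% ± 4%). When two PS realizations exist, their *metric
values* are averaged before correlation (averaging masks would create a
segmentation neither realization produced).

## Exclusion rules

Lesions are excluded when the MS volume is below 2 cm³ (PET resolution
and misregistration sensitivity) or the MS mean AD is below 5 Gy (no
uptake). Both rules evaluate on MS quantities only, so the selection is
identical for every segmentation method.

## Problem sizes and what the validation shows

The shipped validation (`run_phantom_acceptance()`, also driven by
`scripts/acceptance.R` and the test suite) uses the three-phantom
suite — five lesions of 8–60 cm³ on grids of roughly 50×50×50 voxels —
and cohorts of 3–8 simulated patients with up to four lesions; these
sizes keep a full run in minutes on one CPU while leaving every
algorithmic path exercised. On that suite the gradient segmentation
recovers volumes within ~6% (bound 15%), dose metrics within ~5%
(bound 11%), DSC ≥ 0.97 (bound 0.86), MDA ≤ 0.35 mm (bound 1.5 mm),
and jittered repeats are bit-identical (bounds: DSC ≥ 0.99, metrics
within 2%). Those numbers say the *method as implemented* meets the
accuracy envelope on clean, ground-truthed geometry at realistic blur
and noise; they do not certify performance on clinical images, where
motion, reconstruction artifacts and true anatomic ambiguity degrade
both segmentations.
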