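---
title: "Mapping vessel orientations and their alignment with white-matter fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping vessel orientations and their alignment with white-matter fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasofiber)
```

## The problem

Cerebral white matter is supplied and drained by medullary vessels that
penetrate from the cortical surface toward the ventricles. How these
vessels are oriented relative to the axon bundles they traverse matters
for perivascular transport models, for susceptibility-based MRI contrast,
and for interpreting vascular pathology. `vasofiber` quantifies this
relationship from two co-registered inputs:

* a susceptibility-weighted image (SWI), in which veins (and, via inflow
  effects, some arteries) appear as dark or bright tubular structures, and
* a fiber orientation distribution (FOD) field from diffusion MRI,
  expressed in even-order real spherical harmonics (SH), whose lobes point
  along the axon populations present in each voxel.

The output is a set of angle maps in degrees on `[0, 90]`: per voxel, the
angle between the local vessel axis and either the *dominant* FOD peak
(the largest apparent fiber density) or the *nearest* peak (the minimum
over all retained peaks). The distinction carries the scientific content:
a vessel may ignore the dominant fiber direction of a crossing voxel yet
run exactly along its secondary population, which only the nearest-angle
map reveals.

## Processing model

### SWI contrast

Each repetition contributes a magnitude and a phase volume. The phase is
high-pass filtered by homodyne demodulation: the complex image is divided
by a low-pass copy obtained by windowing k-space with a separable Hanning
window, and the phase of the quotient is kept. The filtered phase is
mapped to a multiplicative mask — `(pi + phi) / pi` for negative phase,
1 otherwise — raised to the 4th power, and multiplied into the magnitude.
Repetitions are averaged voxel-wise.

Choices the data do not fix, and what we chose:

* **Window size.** The Hanning low-pass keeps a central k-space fraction
  of 0.25 per in-plane axis by default (`window_fraction`); typical
  homodyne processing uses a central window of roughly this size, and the
  result is insensitive to the exact value for structures much smaller
  than the window scale.
* **2D vs 3D.** Filtering is slicewise (2D) by default, matching the 2D
  acquisitions such data usually come from; `slicewise = FALSE` gives the
  3D variant.
* **Mask polarity.** We adopt the standard negative-phase mask
  (paramagnetic veins carry negative phase under the usual sign
  convention); `polarity = "positive"` is available for data with the
  opposite convention.
* The mask power applies to the normalized mask, not the raw phase, so
  the weights stay in `[0, 1]` for any power.

### Vessel detection and orientation

Tubular structures are enhanced with the multiscale Frangi vesselness
filter. At each scale sigma the image is convolved with Gaussian
derivatives (reflect padding), the Hessian is gamma-normalized by
sigma^2, and its eigenvalues are sorted by magnitude
(|l1| <= |l2| <= |l3|). Ratios `RA = |l2|/|l3|`, `RB = |l1|/sqrt(|l2 l3|)`
and the norm `S` enter the usual exponential combination; dark tubes
require `l2, l3 > 0`, bright tubes the reverse, and `"both"` (the
default) takes the voxel-wise maximum of the two polarities. The
eigenvector of the smallest-magnitude eigenvalue at the best scale is the
vessel axis.

Defaults: `alpha = beta = 0.5` and `c` set to half the maximal Hessian
norm per scale (the filter's original heuristics); scales
`{0.2, 0.4, 0.8, 1.2}` mm suit a 0.2 mm input and should be rescaled with
the voxel size. The vesselness threshold is applied after rescaling the
response to `[0, 1]` per volume, default 0.5 — deliberately conservative
(specificity over sensitivity), and exposed as `vessel_threshold` since
any such cutoff is empirical. Segmentation is restricted to the white
matter mask, and voxels within 3 dilation steps (6-connected) of gray
matter or CSF are removed to suppress partial-volume contrast at tissue
boundaries.

Per-voxel axes are pooled onto a 2 mm isotropic grid: each coarse voxel
receives the *dyadic mean* of the axes of all vessel voxels in its patch,
weighted by vesselness by default (`pool_weighting = "uniform"`
disables the weighting; pooling is an average of sign-ambiguous axes
either way, and the weighting choice moves results very little on
phantoms).

### Why the dyadic mean

Axes are sign-ambiguous: v and -v are the same orientation, so arithmetic
vector averaging is ill-defined (it can cancel identical axes stored with
opposite signs). The standard axial-statistics mean is used instead: the
principal eigenvector of the mean outer-product tensor
`sum_i w_i a_i a_i^T / sum_i w_i`. It is invariant to any sign flips and
to input order. When the two leading eigenvalues tie (e.g. two equal
orthogonal bundles in one patch) the mean axis is not unique; any leading
eigenvector is returned and a `degenerate` flag is set, since true ties
essentially only arise in designed inputs.

### FOD peaks

The SH series is evaluated in a real, orthonormal, even-order basis
(`sin`-terms before `cos`-terms within each degree; a converter to the
opposite ordering is provided since external toolchains differ). Peaks
are found by ascending the spherical function from each of 100
deterministic spherical-Fibonacci hemisphere seeds with a damped Newton
iteration in the local tangent plane (finite-difference gradient and
Hessian; pure Newton steps only where the Hessian is negative definite,
gradient ascent otherwise; steps capped at 0.2 rad; convergence when the
angular step falls below 0.01 degrees, at most 50 iterations). Converged
directions must pass a local-maximum check against a 1-degree ring of
neighbours, which rejects walkers stalled at saddles or minima. Maxima
closer than `min_separation_deg` (default 15 degrees) are merged keeping
the larger; peaks below 10% of the largest amplitude are discarded; at
most three peaks per voxel are kept, sorted by amplitude with exact ties
broken by canonical-sign lexicographic order for determinism.

The seed set is generated at run time rather than shipped as a fixture: a
spherical Fibonacci set is deterministic and its worst-case seed-to-seed
spacing at n = 100 is comparable to an electrostatic-repulsion set, which
is all the search needs (every attraction basin of a retained lobe at the
default kernel widths spans far more than the ~20 degree seed spacing).

### Angle maps and summaries

Angles are `acos(|u . v|)` in degrees, clipped into `[0, 1]` before the
arccos so rounding never produces NaN. A voxel enters a map only when
both a vessel axis and at least one FOD peak exist there; missing voxels
are excluded from all statistics rather than zero-filled, since zeros
would pile mass onto the parallel bin of every histogram. Histograms use
2-degree bins by default. Region summaries aggregate per atlas label
(mean, median, quartiles for both maps).

### Along-tract profiles

Streamline bundles give one fiber orientation per voxel — the dyadic mean
of the unit tangents (central differences, one-sided at the ends) of all
points in the voxel. For profiles, every streamline is resampled to 100
equidistant arc-length points; at point k the angle between the local
tangent axis and the vessel axis of the containing voxel joins segment
k's pool, and segment statistics (mean, min, max, n) are reported.
Correspondence across streamlines is by arc-length index after flipping
any streamline whose endpoints disagree with the bundle's start/end
centroids; point-wise angles are pooled per segment (rather than one
angle per streamline from averaged tangents), which weights each
streamline equally and keeps per-segment extrema meaningful.

### Population maps

Per-subject vessel fields in a common space are reoriented with the
preservation-of-principal-direction rule — for a single axis this is
`a -> normalize(J a)` with the local Jacobian `J` of the warp — and then
combined per voxel: dyadic mean across subjects with at least two valid
contributions, plus the mean angular deviation of subject axes about that
mean as the across-subject variability map. The deviation is measured
about the population mean (not pairwise; `dispersion = "pairwise"` is
available) and subjects are unweighted, since per-voxel vessel counts are
a property of each subject's segmentation rather than evidence about the
population orientation.

## The synthetic phantoms

The generator module supplies every input the pipeline consumes, with
exact ground truth, and is itself part of the tested surface:

* **Tube phantoms** render line, arc, or helix centerlines with Gaussian
  or hard radial profiles, signed contrast (negative = dark vessel), and
  additive Gaussian noise (Rician optional — Gaussian is the default for
  analytic tractability; at the SNR ~ 10 conditions used here the two
  differ negligibly away from the background floor). Truth records the
  nearest-centerline tangent for every voxel within one radius, with
  overlaps resolved toward the locally strongest tube.
* **SH fields** superpose axially symmetric lobes with analytic even-SH
  coefficients (`c_lm = exp(-t l (l+1)) Y_lm(mu)`, the addition theorem
  applied to a zonal kernel), so lobe maxima sit exactly on the
  configured axes. The default sharpness `t = 0.02` gives a lobe FWHM of
  roughly 32 degrees at `lmax = 8`: close to the sharpest width the
  truncation can represent, while keeping truncation sidelobes below the
  10% relative-amplitude cut so ringing never masquerades as a fiber
  population. Configured populations closer than 30 degrees
  are rejected because their combined surface would not have separable
  maxima — mirroring the 15-degree peak-merge floor with margin.
* **Bundles** are rigid cross-section offsets of a centerline with known
  analytic tangents.
* **The crossing scenario** lays all pieces on one grid: a parallel
  region (single fiber along z, tubes along z), a 60-degree crossing
  region (dominant fiber 0.65 along x, secondary 0.35 at 60 degrees,
  tubes along the *secondary* axis), and an orthogonal region (fiber
  along x, tubes along z). The designed region values — nearest ~ 0 and
  dominant ~ 60 in the crossing block, both ~ 0 and both ~ 90 in the
  controls — realize the pipeline's headline contrast end-to-end.

What the phantoms do *not* emulate: physical susceptibility dipole
fields and their B0-orientation dependence, Rician noise floors in dark
vessels, super-resolution artifacts, registration error between the SWI
and diffusion grids, and curving fiber fan/bending within a voxel.
Passing tests therefore demonstrate that the *processing* recovers known
geometry under realistic contrast and noise, not that scanner data meet
the phantoms' assumptions.

## Numerical choices and degenerate inputs

* Gaussian-derivative kernels are truncated at 4 sigma with mirror
  boundaries; derivatives are taken in mm so anisotropic voxels are
  handled.
* Constant (including all-zero) images return all-zero vesselness rather
  than erroring.
* All-zero SH coefficients yield an empty peak list; negative-amplitude
  "peaks" (possible after deconvolution) are discarded.
* Zero-length streamlines are skipped with a warning; bundles entirely
  outside the valid vessel field yield an all-missing profile with a
  warning.
* Singular Jacobians invalidate the affected voxels (with a count) rather
  than propagating NaN.
* Problem sizes in the test-suite and acceptance phantoms (96^3 fine
  voxels at 0.5 mm, 10,242-direction oracle grids, 50-200 random voxels
  per property) were chosen as the smallest sizes at which the geometry
  being tested — multi-voxel tube ridges, 2 mm pooling patches, separated
  FOD lobes — is properly resolved.

## Known limitations

* Veins and arteries are not distinguished; everything that produces
  tubular SWI contrast counts as "vasculature".
* Vessel centerline tracing / graph extraction is out of scope; the unit
  of analysis is the voxelwise axis field.
* Registration, tissue segmentation, spherical deconvolution, and
  tractography are consumed, not computed: the package expects
  co-registered inputs and transforms orientations (not SH coefficients)
  under externally supplied warps.
* The vesselness threshold remains empirical; results at low SNR are
  sensitive to it, which is why it is a first-class config parameter.

## A worked miniature

```{r example, eval = FALSE}
sc <- make_crossing_scenario(seed = 7)
res <- run_subject(list(swi = sc$swi, wm_mask = sc$wm_mask,
                        gm_mask = sc$gm_mask, csf_mask = sc$csf_mask,
                        sh = sc$sh, atlas = sc$atlas,
                        bundles = list(main = sc$bundle),
                        fine_voxel_mm = sc$fine_voxel_mm),
                   run_config(frangi_scales = c(0.5, 0.8, 1.2),
                              vessel_threshold = 0.3))
res$regions
autoplot(res$histograms$dominant)
autoplot(res$profiles$main)
```

The crossing region's summary row shows the signature result: a nearest
angle near zero next to a dominant angle near the designed 60 degrees.
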