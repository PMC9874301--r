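---
title: "Dual-resolution microCT morphometry: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-resolution microCT morphometry: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bonemorph)
```

## The measurement problem

In vivo microCT lets the same animal's subchondral bone be followed over
time, but at a coarser voxel size and lower signal-to-noise ratio than ex
vivo scanning of the excised joint. Every 3D morphometric parameter is a
nonlinear functional of a segmented voxel grid, so coarsening the grid does
not merely add noise: partial-volume blending removes thin trabeculae below
threshold (depressing bone volume fraction, trabecular number and
connectivity), while the surviving structures are measured thicker and the
marrow spaces wider. `bonemorph` packages the complete measurement chain —
image simulation, preprocessing, region-of-interest construction, the ten
standard morphometric parameters, and the paired agreement statistics — so
this resolution bias can be quantified end to end on synthetic bone whose
ground truth is known exactly.

Because the original scans behind such studies are rarely deposited, the
package treats the *synthetic cohort generator as a first-class module*: it
emulates paired acquisitions of the same microstructure at 4.35 um ("ex
vivo") and 10.4 um ("in vivo") voxel size, and all validation rests on
phantoms with closed-form or high-resolution ground truth.

## The phantom model

### Trabecular foam

The trabecular compartment is a level set of a stationary Gaussian random
field with squared-exponential covariance. The field is evaluated by a
randomized spectral (cosine) expansion, so the phantom is a *continuous*
solid: it can be sampled on any acquisition grid directly, and comparing two
resolutions never involves resampling one raster onto another — resolution
effects are therefore never confounded with interpolation artifacts.

Two numerical choices matter here:

* **Spectral stratification.** With a modest number of cosine terms (64 by
  default, keeping evaluation affordable), i.i.d. Gaussian frequency draws
  leave visible directional artifacts: the measured degree of anisotropy of
  a nominally isotropic foam came out around 1.25. Frequency *directions*
  are therefore a quasi-uniform Fibonacci lattice and frequency *magnitudes*
  are stratified chi(3) quantiles with random within-stratum jitter; phases
  remain uniform. This restores statistical isotropy (measured DA 1.09-1.11)
  while the field stays marginally Gaussian and seeded-deterministic.
* **Quantile calibration.** The level-set threshold is the empirical
  quantile of the field matching the target volume fraction, estimated from
  200,000 seeded sample points, so the covered fraction hits the target
  within about 0.01 regardless of the finite-expansion marginal.

Default foam parameters — target BV/TV 0.35, correlation length 33 um —
were chosen once so that the *ex vivo* pipeline reads trabecular
thicknesses near 65 um and bone volume fractions in the mid-30% range,
the scale of murine subchondral trabecular bone. Anisotropy is introduced
by stretching the field along one axis (dividing the corresponding
frequency components), and a DMM-like group contrast by scaling the
correlation length, volume fraction, stretch or plate thickness of the
second group's generator.

### Cortical plate

The subchondral plate is a solid slab of constant thickness capping the
foam, separated from it by a thin marrow gap and from the domain top by an
air gap. The plate is *tilted* (default slope 0.25 along x, 0.08 along y),
for two reasons. First, condyle surfaces are oblique to the scan axis in
real joints. Second — and numerically decisive — a perfectly flat,
axis-aligned plate is a degenerate input for maximal-sphere thickness: the
Euclidean distance transform quantizes distances to integers along the
plate normal, so measured thickness snaps to *even* voxel counts and a
plate spanning an odd number of voxel layers is read one full voxel too
thick. At 10.4 um voxels this alone produced a spurious +7% "in vivo
error". The tilt sweeps the plate boundary through every subvoxel phase,
which restores the averaging that any non-degenerate geometry enjoys; with
it, cortical thickness agrees across the two resolutions to within about
2-4%, mirroring the near-resolution-independence of plate thickness
reported for real scans. Undulating (sinusoidally curved) plates were
rejected: at the in vivo scale the 10-pixel 2D closing operation bridges
the in-plane bands such a plate produces in transverse slices, biasing the
measurement upward.

### Analytic validation shapes

Slabs, cylinders, spheres, tori, parallel-plate stacks and planar rod
lattices carry closed-form ground truth (thickness, surface area, Euler
characteristic, first Betti number, SMI class values). Validation fixtures
place centers on lattice points and use integer-voxel dimensions where
possible, so that estimator error is not confounded with the irreducible
half-voxel placement ambiguity of digitized solids; a 2 um rasterization
serves as the oracle where no closed form exists. Phantom domains are
required to span at least four times the largest feature.

## The acquisition model

Per-voxel bone fraction is computed by supersampling the implicit solid
(2^3 subsamples by default), mapped affinely to grey values (background 40,
bone 220), blurred by an isotropic Gaussian point-spread function, and
corrupted by seeded additive Gaussian noise. Defaults: PSF sigma 0.6 voxel
and noise 5% of contrast ex vivo, versus 1.0 voxel and 10% in vivo — the in
vivo arm is strictly worse, which is the ordering the measurement problem
assumes; the exact noise figures are package choices (no published values
exist for the instruments) and are overridable in the acquisition spec. No
projection physics, beam hardening or ring artifacts are modelled.

## Preprocessing choices

* **Smoothing**: discrete 3x3x3 Gaussian kernel, sigma 0.65 voxel,
  renormalized after truncation; borders replicate edge voxels.
* **Thresholding**: 256-bin histogram, 5-bin moving average, the two
  highest local maxima at least 25 bins apart; the threshold is the mean of
  the two peak grey levels. A second peak is accepted only if the valley
  between the peaks drops below half the smaller peak height — this is what
  lets the procedure *fail loudly* on unimodal input instead of latching
  onto a noise bump in the tail. The comparison is `grey >= threshold`
  (bone inclusive); the returned threshold is equivariant under affine
  rescaling of the greys.
* **Component filtering**: 6-connectivity labeling; either keep the largest
  component (the stand-in for stripping femur, fibula and menisci) or drop
  components strictly below 10 voxels (despeckling; a 10-voxel island is
  kept).
* **Registration**: rigid, maximizing normalized mutual information
  (32-bin joint histogram, out-of-overlap voxels excluded) over a 3-level
  block-averaged pyramid with a derivative-free Nelder-Mead optimizer. Two
  robustness devices are part of the design: a deterministic lattice search
  over +/-6 degrees and +/-6 voxels at the coarsest level seeds the
  optimizer inside the basin of attraction (foam-textured images have a
  severely multimodal NMI landscape; plain identity starts failed at 10
  degree offsets), and the metric is evaluated on a strided subgrid capped
  at 1e5 voxels per level (the moving image is still interpolated
  continuously, so subvoxel sensitivity is retained). Rotations are
  intrinsic Z-Y-X angles in degrees about the volume center; world
  coordinates are `origin + index * spacing` with the origin at the first
  voxel center. Final resampling uses Lanczos-3 windowed-sinc
  interpolation; known-transform recovery on a 128^3 composite phantom is
  accurate to about 0.02 voxel, far inside the half-voxel acceptance band.
* **Contour interpolation**: polygons drawn every few slices are converted
  to per-slice signed distance fields (exact point-to-segment distances);
  linear interpolation of the fields between knots defines intermediate
  masks. Interpolation is exact on contoured slices and monotone: enlarging
  every contour never shrinks the mask.

## Morphometry numerics

* **Thickness / separation** follow the maximal-inscribed-sphere
  definition: exact Euclidean distance transform
  (Felzenszwalb-Huttenlocher), sound distance-ridge pruning (a sphere is
  discarded only when a neighbor's sphere provably contains it), and
  largest-first sphere painting. A sphere also claims voxels whose centers
  lie within half a voxel of its boundary, which removes the systematic
  half-voxel under-read of curved structures; slab, cylinder and sphere
  fixtures are then recovered within half a voxel. Separation is the same
  map applied to the ROI minus bone. The residual accuracy limit of any
  binary-input thickness estimator — a digitized boundary is only known to
  within half a voxel — is inherited by all downstream parameters and is
  part of what the resolution-bias experiment measures.
* **Surface area** is a genuinely triangulated isosurface: marching
  tetrahedra (six tetrahedra per cell, case-by-case triangulation) on the
  signed Euclidean distance field, whose zero level sits midway between
  boundary voxel centers. The raw discrete field has a corrugated level set
  that overestimates a sphere's area by ~12%; a light Gaussian smoothing of
  the field (sigma 0.8 voxel) flattens the corrugation and brings sphere
  area within 0.5% of 4 pi r^2. The same field and mesh serve BS/BV and
  SMI for consistency.
* **SMI** is `6 * BV * S' / S^2` with the area derivative taken by
  offsetting the level set half a voxel *outward* along the field — the
  level-set form of displacing mesh vertices along their normals, robust to
  mesh degeneracies because no explicit mesh connectivity is needed. The
  smoothed field is not exactly unit-gradient, so the offset level is
  scaled by the mean gradient magnitude near the surface; without this
  calibration the sphere's SMI reads 4.45 instead of 4.03. Reference
  plate, rod and sphere land within 0.3/0.3/0.4 of 0/3/4.
* **Anisotropy** uses mean intercept lengths along 512 quasi-uniform
  directions (Fibonacci hemisphere), each sampled by a bundle of parallel
  lines (2-voxel spacing, half-voxel steps, nearest-neighbor lookup). A
  second-rank tensor is fit by least squares to `1/MIL^2`; DA is the ratio
  of the longest to the shortest semi-axis of the resulting ellipsoid, 1 for
  isotropy. Directions crossing no interface are dropped from the fit.
* **Connectivity density**: the mask is purified (largest 26-connected
  component kept, cavities not reaching the array border filled), the Euler
  characteristic is computed exactly as vertices - edges + faces - cubes of
  the closed voxel complex (the 26-connected-foreground convention), and
  connectivity = 1 - chi is then the first Betti number. Conn.D divides by
  ROI volume in mm^3. Ball, torus and g-handle lattices are exact.
* **Cortical thickness**: 2D closing with a Euclidean disc (pixel included
  iff its center is within the radius), applied within the cortical ROI
  only, then the mean thickness map over plate voxels. The ROI's bounding
  box is cropped in-plane only, so the distance transform always sees both
  plate faces.
* **Tb.N** is `(BV/TV) / Tb.Th` with thickness in mm — the convention that
  reproduces published trabecular numbers from published BV/TV and Tb.Th
  group means to the printed digit (0.333 / 0.069 mm = 4.83 ~ 4.8 1/mm) —
  not the inverse-separation definition.

## Statistical conventions

Paired accuracy uses the two-sided paired t-test; the per-specimen percent
difference is the *mean of ratios* `mean(100 * (in - ex) / ex)`, not the
ratio of means — the two disagree on skewed data, and only the former is
consistent with published table internals. Bland-Altman limits are exactly
+/- 2 SD of the differences (not 1.96). Agreement regressions are ordinary
least squares with R^2 the squared Pearson correlation. Normality of the
paired differences uses the Lilliefors statistic with a *seeded Monte-Carlo
null* (10,000 replicates by default, cached per sample size) rather than an
analytic approximation. Group contrasts are two-sided two-sample t-tests
with pooled variance by default (the classical default of the function
family named in the protocol); Welch is available behind a flag. No
multiple-testing correction is applied: each parameter is judged at p <
0.05, and the report footer says so.

## Problem sizes

The shipped validation and acceptance runs use: 850 um cubic cohort domains
(195^3 ex vivo / 81^3 in vivo voxels, 8 paired phantoms), a 128^3 composite
phantom with 20 random transforms for registration recovery, analytic
phantoms of 97-259 voxels per side for the morphometry oracles, and 200
replicates of 2,000 Monte-Carlo samples for the Lilliefors null. These
sizes were chosen so the whole suite runs comfortably on a single CPU while
keeping every tolerance diagnostic rather than generous.

## What the phantoms do not show

The Gaussian-field foam reproduces the scale, volume fraction and
connectedness of trabecular bone but not its full architecture: real
trabeculae are a mixture of plates and rods with higher
separation-to-thickness ratios (the foam's Tb.Sp runs ~90 um at BV/TV 0.35
where real subchondral bone shows ~165 um at similar BV/TV), and real SMI
values are lower. Consequently the *signs* and the qualitative ordering of
the resolution biases transfer to real data, and are what the acceptance
suite asserts; the *magnitudes* (e.g. a -5 percentage-point BV/TV deficit)
are specific to the phantom family. Scanner physics beyond Gaussian blur
and additive noise — beam hardening, rings, motion — are out of scope, as
are cartilage, menisci and osteophytes. Between-modality registration is
validated by known-transform recovery, not against an external reference
implementation, and the MIL/SMI estimators claim phantom-validated
tolerances rather than numeric identity with any vendor software.
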