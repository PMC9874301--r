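# bonemorph

Dual-resolution microCT morphometry of subchondral bone.

## The problem

In vivo microCT makes it possible to follow the subchondral bone of the
same mouse knee over time — a longitudinal design that cuts measurement
variability and the number of animals needed in osteoarthritis studies.
The price is resolution: an in vivo scan of the proximal tibia is acquired
at roughly 10.4 µm voxels, against 4.35 µm for ex vivo scanning of the
excised joint. Because every 3D morphometric parameter is a nonlinear
functional of a segmented voxel grid, the coarser grid does not just add
noise; partial-volume blending pushes thin trabeculae below threshold and
biases each parameter in its own direction.

`bonemorph` is for bone and osteoarthritis researchers who want to
quantify, on fully known synthetic ground truth, how much each parameter
is biased at the in vivo resolution, with the complete processing chain
used in such studies:

* **Synthetic cohorts** — implicit-geometry phantoms (Gaussian-random-field
  trabecular foam under a tilted cortical plate, plus analytic slabs,
  cylinders, spheres, tori, plate stacks and rod lattices with closed-form
  ground truth), imaged at both voxel sizes with modality-specific blur and
  noise.
* **Preprocessing** — 3×3×3 Gaussian smoothing (σ = 0.65 voxel), automatic
  two-peak global thresholding, 6-connectivity component filtering,
  despeckling (< 10 voxels), rigid registration by normalized mutual
  information with Lanczos-3 resampling.
* **Regions of interest** — shape-based interpolation of sparse planar
  contours, medial/lateral compartment splitting, fixed 500 µm cortical
  boxes, 2D pore closing (disc radius 10 px).
* **Morphometry** — the standard parameter suite on a binary volume within
  an ROI:

  | symbol | quantity | method |
  |---|---|---|
  | BV/TV | bone volume fraction (%) | voxel counting |
  | BS/BV | bone surface density (1/mm) | marching-tetrahedra isosurface |
  | Tb.Th | trabecular thickness (µm) | maximal inscribed spheres (EDT) |
  | Tb.Sp | trabecular separation (µm) | same, on the marrow phase |
  | Tb.N  | trabecular number (1/mm) | (BV/TV)/Tb.Th |
  | DA    | degree of anisotropy (–) | mean-intercept-length fabric tensor |
  | SMI   | structure model index (–) | surface-dilation derivative |
  | Conn.D | connectivity density (1/mm³) | Euler characteristic, 1 − χ |
  | Ct.Th.Med/Lat | cortical plate thickness (µm) | closing + inscribed spheres |

* **Paired accuracy statistics** — paired t-tests, per-specimen percent
  differences, agreement regressions (R²), Bland–Altman limits at ±2 SD,
  Monte-Carlo Lilliefors normality, and two-sample group contrasts,
  assembled into table-style reports.

## Worked example

Simulate one synthetic animal, image it at both resolutions, and run the
full measurement chain:

```r
library(bonemorph)
# one synthetic animal: trabecular foam capped by a tilted cortical plate
spec <- animal_phantom_spec(seed = 42)
phantom <- make_phantom(spec)

# paired acquisitions of the same bone at the two study resolutions
ex <- simulate_acquisition(phantom, acq_ex_vivo(seed = 43))   # 4.35 um
iv <- simulate_acquisition(phantom, acq_in_vivo(seed = 44))   # 10.4 um
print(ex)
#> <grey_volume> 195 x 195 x 195 voxels @ 4.35 um, origin (2.175, 2.175, 2.175)
#>   grey range [-7.604, 263.2]

# automatic two-peak threshold, despeckling, then the full parameter suite
results <- rbind(
  measure_all(segment_volume(ex), animal_rois(ex, spec),
              specimen = "m42", modality = "ex_vivo"),
  measure_all(segment_volume(iv), animal_rois(iv, spec),
              specimen = "m42", modality = "in_vivo"))
wide <- reshape(results[results$roi %in% c("trabecular-whole",
                                           "cortical-medial"),
                        c("parameter", "modality", "value")],
                direction = "wide", idvar = "parameter",
                timevar = "modality")
print(wide, digits = 3, row.names = FALSE)
#>  parameter value.ex_vivo value.in_vivo
#>      BV/TV        43.793        43.143
#>      BS/BV        57.504        47.517
#>      Tb.Th        66.584        76.335
#>      Tb.Sp        67.784        77.214
#>       Tb.N         6.577         5.652
#>         DA         1.239         1.309
#>        SMI         2.596         3.007
#>     Conn.D       661.751       340.101
#>  Ct.Th.Med       153.286       161.159
```

Reading the output: this is the resolution bias on a single specimen — the
in vivo arm reads a lower bone volume fraction, trabecular number and
connectivity density, and a higher trabecular thickness and separation,
because thin trabeculae blur below threshold at 10.4 µm while the
survivors are measured thicker. Cortical plate thickness is nearly
unchanged, as the plate is many voxels thick at either resolution. Across
a cohort (`generate_paired_cohort()` + `run_cohort_analysis()`), these
per-specimen differences become the paired statistics of the accuracy
report, and `validate_phantoms()` prints the oracle table checking every
estimator against closed-form phantom truth.

A command-line front end wrapping the same functions is installed at
`inst/cli/bonemorph.R` (subcommands `simulate`, `preprocess`, `measure`,
`compare`, `validate`).

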