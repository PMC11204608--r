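# ctfootprint

3D morphometry of muscle-attachment footprints from CT volumes.

Anatomical studies can measure where muscles attach to bone by dissecting
the attachment, painting its bony footprint with radiopaque barium-sulfate
paint, CT-scanning the specimen, and reconstructing bone and paint from the
images.  `ctfootprint` implements that measurement chain for R users —
anatomists and biomechanists building attachment databases for
musculoskeletal models:

* **Segmentation**: Hounsfield-unit window thresholding (bone window
  250–3000 HU, secondary paint threshold 2000 HU) and watertight isosurface
  extraction by marching tetrahedra.
* **Coherent models**: landmark-initialized ICP registration of repeat-scan
  surfaces, point-to-surface deviation analysis, welding, hole filling and
  volume-conserving Taubin smoothing.
* **Anatomy**: the ISB femoral frame (origin at the transepicondylar-axis
  midpoint, y cranial toward the head, z lateral, x anterior); per-bone
  volume, surface area and centre of gravity; femoral morphometrics — the
  mechanical-axis length MA, transepicondylar-axis length TEA, femoral head
  diameter FHD (least-squares sphere fit) and shaft diameter SD
  (equivalent-circle diameter 2·√(A/π) of the mid-shaft cross-section).
* **Footprints**: automated tracing of the paint contact area onto the bone
  surface, footprint area, area-weighted centroid, best-fit plane, and the
  *breakthrough point* — the piercing point of the centroid-normal line with
  the attachment surface, the single-point hand-off to musculoskeletal
  models; subdivision rules for linear (thirds) and compound (2×3)
  attachments.
* **Cohort statistics**: mean, population standard deviation (divisor *n*)
  and coefficient of variation CV = 100·STD/mean, rendered as report
  tables.
* **Synthetic specimens**: implicit-primitive phantom bones, paint patches
  with analytic ground truth, voxelized CT volumes and multi-specimen
  cohorts, so the whole pipeline is testable without any cadaver data.

## Worked example

```r
library(ctfootprint)

# a synthetic femur whose construction matches the reference cohort means
bone <- make_synthetic_bone("femur", list(head_radius = 25), seed = 2)
fm   <- measure_femur(bone$mesh, bone$landmarks)
fm
#> FemoralMorphometrics: MA 405.38, TEA 91.65, FHD 49.96, SD 35.69 mm

# paint a 30-degree spherical cap on the femoral head and trace it back
paint <- make_paint_patch(bone, "cap",
                          list(primitive = "head", axis = c(0, 1, 0),
                               theta = pi / 6))
paint$truth_area                    # analytic: 2*pi*25^2*(1 - cos(pi/6))
#> [1] 526.117

fp <- trace_contact_area(bone$mesh, paint$mesh, epsilon = 0.5)
fp
#> Footprint 'attachment' (origin): 526.9 mm^2, 7537 faces
fp$breakthrough_point               # pierces the cap near its apex
#> [1]   0.03823091 430.66617473   0.03948074

# population statistics as used in the report tables
population_stats(c(430.40, 403.70, 442.10, 345.30))
#> SummaryStats: n = 4, mean 405.3750, STD 37.3724, CV 9.22%
```

The traced area (526.9 mm²) recovers the analytic cap area (526.1 mm²)
within 0.2%, and the breakthrough point lands within 0.3 mm of the cap apex
at (0, 430.38, 0) — the head centre sits at y = 405.38 with radius 25.

A full synthetic study — repeat "scans" with repositioning and noise,
segmentation, registration, deviation tables, morphometrics and footprint
tables for a four-specimen cohort (three left, one right) — runs with:

```r
res <- run_pipeline(config = pipeline_config(seed = 1), out_dir = "results")
res$tables$femoral
```

A thin command-line wrapper with `simulate`, `segment`, `align`,
`deviation`, `footprint`, `stats` and `run` subcommands is installed at
`inst/cli/ctfootprint.R`.

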