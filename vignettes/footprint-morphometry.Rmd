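---
title: "CT-based footprint morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-based footprint morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Musculoskeletal models usually reduce a muscle attachment to a single point,
although real attachments are extended, individually varying regions on the
bone surface.  One way to measure them is to dissect the attachment, paint
its bony footprint with a radiopaque barium-sulfate paint, CT-scan the
specimen, and reconstruct both the bone and the paint from the image volume.
This package implements that measurement chain as reusable, tested code:

1. **Segmentation** — Hounsfield-unit (HU) window thresholding of the CT
   volume and isosurface extraction of bone and paint surfaces.
2. **Coherent model building** — rigid registration of repeat-scan surfaces
   to a reference reconstruction, deviation analysis, cleanup and smoothing.
3. **Anatomy** — an ISB femoral coordinate frame, per-bone volume, surface
   area and centre of gravity, and the femoral morphometrics MA, TEA, FHD
   and SD.
4. **Footprints** — tracing the paint contact area onto the bone,
   computing area, centroid, best-fit plane and breakthrough point, and
   subdividing multi-part attachments.
5. **Cohort statistics** — mean, population standard deviation (divisor
   *n*) and coefficient of variation (CV, percent), rendered as report
   tables.

Because no public dataset accompanies this kind of anatomical study, a
synthetic-specimen generator is a first-class part of the package: every
stage can be exercised against analytic ground truth.

## Synthetic specimens

Bones are modelled as unions of spheres and capsules and meshed by marching
tetrahedra on the implicit indicator function.  The femur is laid out in its
own ISB frame — origin at the transepicondylar axis (TEA) midpoint, y toward
the femoral head, z lateral, x anterior — so that the frame-construction and
morphometric code can be validated against construction parameters.  The
default femur reproduces the reference cohort means: mechanical axis
MA = 405.38 mm, TEA = 91.65 mm, head diameter FHD = 50.93 mm, and shaft
diameter SD = 35.70 mm.

Paint marks are defined analytically on one host primitive:

* **cap** — a geodesic disc on a sphere; area $2\pi r^2(1-\cos\theta)$,
  centroid on the axis at $r(1+\cos\theta)/2$;
* **polygonal** — a star-shaped geodesic region
  $\psi \le \theta(\varphi) = \theta_0\,(1+a\cos k\varphi)$ on a sphere,
  with area and centroid from azimuthal quadrature (4096 nodes, effectively
  exact);
* **linear** — a strip of arc-width $w$ and length $\ell$ on a cylindrical
  shaft, area $\ell w$, enforced aspect ratio $\ge 4$.

The patch *mesh* is a thin shell: the covered bone faces offset outward by
0.15 mm along the primitive normal.  A thin shell (rather than a volumetric
blob) matches how paint and bone blend at the surface in CT images while
keeping the ground truth defined on the bone surface itself.  Shells stay
within 0.5 mm of the bone.

Cohorts draw log-normal multiplicative factors for patch areas (log-normal
because areas are positive and right-skewed; the distribution guarantees
positivity at high CV), surface jitter for patch placement, and log-normal
factors for bone dimensions.  Defaults are the study conditions: four
specimens, three left-sided and one right-sided, attachment-area CV 33%,
femoral-dimension CV 7%, 2 mm placement jitter.  Realized strip widths are
floored at 5 mm — a painted mark much narrower than that is below the
method's resolving scale.  Left specimens are produced by mirroring about
the sagittal plane and are mirrored back into a common right-side convention
before cohort statistics, so attachment coordinates are comparable across
sides.

CT volumes are voxelized analytically from the implicit scene: bone voxels
get 1200 HU, a paint shell within
$\max(\text{thickness}, 0.55\cdot\text{spacing})$ of the painted surface
region gets 2600 HU (letting paint and bone interblend at finite resolution,
as they do in real scans), soft tissue within 12 mm of bone gets 40 HU, the
rest is air at −1000 HU, plus optional additive Gaussian noise.  The paint
HU is chosen above bone so that one primary window (250–3000 HU) captures
both while a secondary threshold (2000 HU) separates them.

## Numerical choices

**Isosurfaces.** Surfaces are extracted by marching tetrahedra (six
tetrahedra per cell sharing the main diagonal), which tiles space
conformally and yields watertight, consistently oriented meshes without a
large case table.  The raw midpoint isosurface of a *binary* grid carries a
well-known surface-area bias (the faceting overestimates area by roughly a
quarter for a voxelized sphere even though the volume is nearly exact), so
`extract_surface()` and the implicit mesher apply one separable box-filter
pass to the indicator field before contouring; this brings the area of a
voxelized sphere within 0.1% of the analytic value at 1 mm spacing.  The
pass is skipped automatically when it would erase structures only one voxel
thick (paint shells), which are contoured from the raw binary field.  With
smoothing off, the 0.5-level surface of a single positive voxel is the exact
midpoint polyhedron: closed, orientable, enclosing half a voxel volume, with
an area between the octahedron ($\sqrt 3$) and the voxel cube (6) — a useful
structural sanity check even though no smooth surface corresponds to it.

**Meshing pitch.** Synthetic bones are meshed at 0.8 mm by default.  The
pitch is a discretization parameter, set so that face-level quantization in
footprint tracing stays below the 3% area-recovery contract for the
narrowest default marks (5–8 mm strips); at 1 mm the narrowest strips
occasionally exceed it.

**Tracing rule.** The paper's manual on-screen tracing is replaced by an
automated proximity rule: a bone face belongs to the footprint when its
centroid lies within `epsilon` (default 0.5 mm, the scale of segmentation
deviation) of the paint surface.  A bare proximity rule dilates the
footprint by a rim of width up to $\sqrt{\varepsilon^2 - t^2}$ beyond the
paint boundary ($t$ the shell offset), which alone costs several percent of
area on elongated marks.  Faces farther than 0.1 mm are therefore accepted
only when their offset direction is aligned with the nearest paint-face
normal (|cos| ≥ 0.9): under the paint the offset is normal to the surface,
while sideways spill past the rim is nearly tangential.  Selected faces keep
their full area (faces are never split), so footprint areas are exact sums
of bone-face areas.  Connected components below 5% of the largest are
dropped as spurious.  Overlapping marks are resolved by assigning contested
faces to the nearer paint surface, with ties going to the lexicographically
first attachment name.

**Best-fit plane and breakthrough point.** The plane through the footprint
centroid minimizes the area-weighted squared orthogonal distance of face
centroids; its normal (smallest-eigenvalue eigenvector of the weighted
covariance) is oriented outward from the bone to make the breakthrough
search deterministic.  The breakthrough point is the intersection of the
centroid-normal line with the footprint nearest the centroid; when the line
misses the surface (annular footprints), the closest surface point is
returned and flagged — so a breakthrough point always lies on the attachment
surface.

**Subdivision.** "Divided three times in length" is read as *three*
equal-length parts cut perpendicular to the proximal–distal chord, and the
vastus-intermedius rule as a 2×3 scheme (one halving plane containing the
chord and the footprint normal, crossed with length-wise thirds, six parts);
this reading is what makes the six stated parts come out.  Faces are
assigned whole by centroid side: child areas then sum *exactly* to the
parent area, at the cost of cut lines ragged by at most one face width.

**Registration.** The original workflow aligned repeat scans in commercial
software without stating the algorithm; the reproducible equivalent used
here is a least-squares (Kabsch) landmark initialization followed by
iterative closest point on a deterministic vertex subsample, converging when
the mean point-to-surface distance improves by less than $10^{-4}$ mm
(cap 100 iterations).  Deviation analysis is one-directional
(test → reference), unsigned, area-uniform sampled, summarized with the
population STD.

**Coherent model.** Repeat-scan reconstructions of the same bone are
near-coincident closed surfaces; naively concatenating them yields nested
shells rather than one surface.  The coherent model is therefore the
cleaned, hole-filled, Taubin-smoothed *reference* reconstruction, while the
repeat scans contribute through registration and the deviation tables —
for phantom data the repeat surfaces add no geometric information beyond
their deviation.  Hole filling closes boundary loops of at most 200 edges
(only small segmentation defects should be auto-closed); Taubin smoothing
uses $\lambda = 0.5$, $\mu = -0.53$ with a volume-restoring rescale about
the centroid, keeping volume drift under 1%.

**Femoral morphometrics.** MA is the distance from the fitted head centre
to the TEA midpoint — the only definition computable from the named
landmarks, and consistent with a frame whose origin is the TEA midpoint and
whose y axis points at the head.  FHD comes from an algebraic least-squares
sphere fit to head-surface vertices (selected around the head-centre
landmark outside a 50° cone toward the neck, with one refinement pass; the
shell radius is seeded by a 5% distance quantile so single rough-mesh
vertices cannot derail it).  SD is the equivalent-circle diameter
$2\sqrt{A/\pi}$ of the shaft cross-section at 50% of MA along y, computed
from the plane-section polygon — rotation-invariant and robust to
non-circular sections.  The ISB z-axis prose in the source description of
this frame is ambiguous (a plane containing the origin and the head centre
is not unique); the standard resolution is used: z is the component of the
medial→lateral epicondylar direction orthogonal to y, sign-flipped for
left-sided input so z stays lateral, and x = y × z.

**Statistics.** All summaries use the population STD (divisor *n*) and
CV = 100·STD/mean.  Report tables render with half-away-from-zero rounding
to 2 decimals; internal values are never rounded.  Two printed reference
summaries are not reproducible from their own printed inputs (the
femur-only deviation mean, printed 0.48 but computing to 0.47, and the
surface-area mean-CV spread, printed 1.55 but computing to 1.56); both were
evidently computed from unrounded data and are documented rather than
chased.

## Problem sizes

The bundled tests and the acceptance script use deliberately scaled
problems: synthetic femora meshed at 0.8 mm (about 10^6 grid cells,
~500k faces), clean-cohort recovery on 5 specimens × 5 patches, CV
calibration on a 200-specimen truth-only cohort, and a full 4-specimen
pipeline at 1.75 mm voxel spacing with two scans per specimen for the
determinism check.  These sizes were chosen as the smallest at which the
stated tolerances are meaningful; all of them run on a single CPU.

## What passing tests do and do not show

The generator emulates the *geometry* of the measurement — HU contrast,
paint/bone interblending at finite voxel size, repeat-scan repositioning,
inter-specimen size and placement variation — with idealized primitive
bones.  It does not emulate trabecular texture, beam hardening, scanner
artifacts, formalin-fixation effects, or genuinely irregular anatomical
surfaces.  Passing the recovery tests therefore shows that the measurement
chain is unbiased and precise on known geometry at realistic contrast and
resolution; it does not certify accuracy on real anatomy, where
segmentation and labeling at the paint contact area remain the dominant,
operator-dependent error source (the deviation analysis quantifies exactly
that).  Footprint areas recovered through the full voxel pipeline at coarse
spacing carry a positive bias from the interblending rim — visible in the
pipeline's own tables and consistent with the largest deviations sitting
under the painted areas in the original workflow.

## Known limitations

* Cap and polygonal marks must sit on a sphere primitive, strips on a
  capsule; marks spanning primitive junctions have no closed-form truth.
* The coherent model is built from the reference scan only (see above).
* The fibular plane-split rule is implemented exactly as specified
  (a plane through the coordinate origin, the footprint centroid and a
  named apex point) via `subdivision_spec("plane_split", ...)`; with the
  origin far from the fibula the geometric intent is unverifiable, so no
  default is provided for it.
* No non-rigid registration, no DICOM, no inferential statistics.
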