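---
title: "Post-segmentation analysis of type A aortic dissection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-segmentation analysis of type A aortic dissection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and data model

`taadmorph` analyses multi-label segmentations of the dissected aorta on
contrast CT. The exchange type throughout is the `label_volume`: a 3D
integer grid indexed `(z, y, x)` with physical voxel spacing in mm, and
the fixed label convention 0 = background, 1 = true lumen (TL), 2 = false
lumen (FL), 3 = intimal flap. NIfTI-1 files store data `(x, y, z)`; the
reader permutes to the internal order and takes spacing from the header.
The flap label never occurs in input data: clinical annotations and
network predictions label only TL and FL, and the flap is *recovered* by
the extraction procedure below, mirroring how such segmentations are
produced in practice.

Slice indices are 1-based, the natural R convention. Whether `z`
increases head-to-foot is deliberately left to the data: all analysis is
per-slice or slice-symmetric, and anatomical direction enters only
through the configured slice range.

## Flap extraction

Each slice with nonempty TL and FL is processed as follows.

1. **Whole-aorta region.** TL and FL are merged into a single region, and
   a closed contour is evolved over it. The engine is a morphological,
   region-based contour evolution on the binary image: the region is
   initialised from the Euclidean closing of the merged lumens (radius
   `init_dilation_mm`, default 3 mm) and iterated with a 3×3 majority
   filter — a discrete curvature-flow step — while being constrained to
   remain a superset of the lumens. Evolution stops when the region is
   unchanged for `convergence_window` consecutive iterations (default 3)
   or after `max_iterations` (default 50, with a warning). Because the
   closing of a radius larger than half the flap gap bridges the gap, the
   converged region is a tight, smooth outer hull of the aorta cross
   section. The literature leaves the specific active-contour energy,
   initialisation and stopping rule for this step unspecified; a
   curvature-regularised morphological evolution was chosen because it is
   parameter-light, robust on binary inputs, and reproduces the intended
   behaviour. A plain Euclidean-closing engine (`engine = "closing"`) is
   kept as a cross-check and debugging path.

2. **Region subtraction.** The flap is the remainder of the aorta mask
   after removing TL and FL. Residual connected components that do not
   touch (8-neighbourhood) both TL and FL are bridging artifacts of the
   outer contour, not flap, and are discarded when
   `adjacency_required = TRUE` (the default). 8-connectivity is used so
   that diagonally adjacent flap pixels count as touching.

The output satisfies the region algebra **aorta = TL ⊔ FL ⊔ flap**
exactly on every processed slice, and re-running the extraction on its
own output reproduces the same flap (idempotence). Slices where TL or FL
is empty carry no flap definition and are copied unchanged with a logged
reason, mirroring the manual exclusion of unusable cross-sections.

## Morphometry

* **Maximum diameter** is the maximum Feret diameter: the largest
  Euclidean distance between any two foreground pixel centres, computed
  exactly via the convex hull. Among the candidate definitions
  (equivalent-circle, caliper placement), only the Feret diameter is
  consistent with a crescent-shaped FL whose longest chord approaches
  the whole-aorta diameter, which is the configuration seen in dissected
  aortas.
* **Areas** are foreground pixel count × pixel area. No 3D obliquity
  correction is applied: measurements are defined per CT slice.
* **Flap thickness** is a medial-axis width: for every pixel of the
  Zhang–Suen skeleton, the distance to the nearest boundary point plus
  the distance to the nearest boundary point on the opposite side, then
  averaged along the skeleton. The boundary is represented at sub-pixel
  precision by the midpoints of pixel edges separating foreground from
  background. Distances to background pixel *centres* would bias the
  width upward by up to one pixel for axis-aligned bands, while distances
  to the pixel-square outline are biased downward at staircase corners of
  oblique bands; the crack-midpoint representation sits between the two
  and keeps the estimator within ~0.2 mm of truth at the reference pixel
  size for band widths of 1.5–3.5 mm. Measuring the two sides separately
  keeps even-width bands, whose true medial axis falls between pixel
  rows, unbiased. A single-pixel line reports one pixel spacing with a
  warning. The simpler area/skeleton-length estimator is retained
  internally as a cross-check.
* **Patient averages** are unweighted means over passing slices (all
  three regions present, and inside the configured slice range, standing
  in for the manually chosen ascending-aorta section; no automatic
  anatomical landmarking is attempted). Patients with no passing slice
  raise a distinct exclusion condition and are dropped with a logged
  reason.
* **Relative errors** are computed per patient, `|pred − gt| / gt`, then
  averaged across patients. The alternative — the relative discrepancy
  of the two across-patient averages — understates the error whenever
  per-patient deviations have mixed sign, and does not reproduce the
  reporting convention of clinical evaluations of this kind.

## Segmentation evaluation

Confusion counts are per-voxel over the gathered 3D volume (not averaged
over per-slice metrics), per label. Accuracy, precision, recall, IoU and
Dice are literal ratio definitions; ratios with a zero denominator are
reported as `NA` with a warning and excluded pairwise from statistics —
coercing them to 0 would silently bias patient averages.

The Hausdorff distance is the exact symmetric max-min distance between
the full voxel-centre sets of the label in the two volumes, in physical
mm, computed with two separable exact Euclidean distance transforms
(Felzenszwalb–Huttenlocher lower envelopes, anisotropic spacing). Full
sets rather than boundary sets are used deliberately: when one set has an
interior cavity the two formulations differ, and only the full-set form
matches the max–min quantifier structure of the definition. Published
tables of this metric often omit units; the package computes mm by
default and voxel-index units behind `units = "voxel"`, so either
convention can be reproduced.

Cross-validation grouping assigns patients to `k` folds (default 4)
of equal-as-possible size, deterministically given a seed. The paired
comparison of two conditions uses per-patient differences: Shapiro–Wilk
normality (valid for 3 ≤ n ≤ 5000) followed by a two-sided paired
t-test at α = 0.05, via the standard `stats` implementations. Identical
differences (zero variance) are an error rather than a silent `t = Inf`.

## The phantom generator

No patient CT data ship with the package, so validation uses a synthetic
dissected-aorta phantom with analytically known morphometry:

* Each axial slice is a filled disc of diameter `outer_diameter` — the
  whole aorta, with zero wall allowance, so aorta = TL ∪ flap ∪ FL by
  construction, matching the three-region algebra of the analysis.
* A straight chord band of width `flap_thickness` at signed offset
  `flap_offset` and orientation `flap_angle` models the intimal flap. The
  band splits the disc into two circular segments; the smaller side is
  TL, which reproduces the clinically typical asymmetry (a compressed
  true lumen). Segment areas follow the closed form
  `R² acos(d/R) − d √(R² − d²)` for the cut distance `d`; maximum chords
  are `2√(R² − d²)` for the minority side and the full diameter once the
  segment contains the centre.
* The tube centre drifts sinusoidally in-plane along `z`
  (`centerline_amplitude`, default 5 mm) so the per-slice machinery is
  exercised on varying geometry; a straight tube under-tests it.
* The **annotation-style** volume leaves the band as background, exactly
  as manual TL/FL annotation does (the flap is not labelled at that
  stage), so the pipeline must rediscover it; a companion **full-truth**
  volume labels the band 3 for scoring flap recovery.
* Degraded "predictions" apply, per slice and per lumen, a random
  Euclidean dilation or erosion up to `boundary_shift_mm` (default
  0.9 mm, about one in-plane pixel), swap `flip_fraction` (default 5%) of
  lumen boundary voxels between TL and FL, and zero `dropout_slices`
  slices. All randomness flows from explicit seeds; nothing touches the
  global RNG state unprotected.

Defaults emulate the reference acquisition: spacing
1.25 × 0.8242 × 0.8242 mm, lumen diameter 50 mm, flap 2.4 mm — the scale
of a dissected ascending aorta. The phantom is deliberately simple: a
circular cross section, a straight chord flap, no false-lumen thrombus,
no branch vessels, arch or fenestrations, and no intensity model in the
analysis path. Passing phantom tests therefore demonstrates that the
geometric measurement and evaluation machinery is correct at clinical
scales and resolutions — not that any segmenter performs well on real
CT, nor that real flap anatomy is chord-like.

## Numerical choices

* Morphology uses true Euclidean structuring elements of physical radius
  in mm, implemented by thresholding the exact distance transform, so
  anisotropic pixels and millimetre-specified radii are handled without
  approximating discs by square brushes. A tolerance of 1e-9 mm absorbs
  floating-point rounding at the threshold.
* Float-stored labels are accepted within 1e-6 of an integer (common in
  segmentation exports); anything else is a format error. Foreign label
  codes can be translated by a CSV remap table at read time.
* Surface meshes are the 0.5 isosurface of the binary label mask on the
  voxel lattice: one quad (two triangles) per exposed voxel face, with
  vertices on the voxel-corner lattice in mm. Voxel pairs touching only
  along an edge would make that surface non-manifold; one empty voxel of
  each such pair is filled first, so every mesh edge is shared by exactly
  two faces and the enclosed volume equals the voxel volume to well
  under 1%. ASCII STL is written one file per label per patient.
* Ties: the largest connected component is selected by pixel count with
  the lowest label winning ties; CCW contour orientation is enforced by
  the sign of the shoelace area.

## Problem sizes

The shipped tests and the acceptance script run on phantoms of 6–24
slices at 96 × 96 pixels and cohorts of 2–10 patients, with 200 random
volume pairs for the metric-formula checks, 50 pairs for the Hausdorff
oracle, and 2000 null replicates (n = 24) for the t-test calibration —
sizes chosen so the whole suite completes in well under a minute while
every check still runs at the reference voxel spacing. The pipeline
itself has no size assumptions beyond memory.

## Known limitations

* The chord-band flap is a geometric idealisation; curvature of real
  flaps is not modelled.
* False-lumen thrombus is not represented; where thrombus is annotated
  as FL, its boundary error contaminates FL-area comparisons.
* Diameters are in-plane; no centreline-based double-oblique correction.
* The contour evolution is designed for binary label images; it is not
  an intensity-driven snake and should not be pointed at raw CT.
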