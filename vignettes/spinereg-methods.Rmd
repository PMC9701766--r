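---
title: "Standing-posture registration of CT-based lumbar spine models: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standing-posture registration of CT-based lumbar spine models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-specific 3D models of the lumbar spine are usually segmented from
CT, which is acquired supine. Standing radiographs, in contrast, show the
spine under physiological load, and the sagittal parameters read from them
— above all the lumbar lordosis (LL), the angle between the cranial
endplate of L1 and the cranial endplate of S1 — differ systematically from
the supine configuration. `spinereg` implements a contour-based rigid
2D-3D registration that carries CT-derived vertebra meshes into the pose
shown by a pair of calibrated standing radiographs (frontal + sagittal),
so that the resulting 3D model carries the standing alignment. Because each
vertebra is a rigid bone, a per-vertebra rigid transform is the exactly
appropriate model class; no deformable registration is involved.

The package also implements the measurements used to judge such a
registration: postregistrational midsagittal sections with intersegmental
and LL angle measurement, Dice similarity of voxelized meshes, Metro-style
mean surface distances, Hausdorff distances, and two-way mixed-effects
absolute-agreement intraclass correlation coefficients (ICC). A parametric
synthetic spine generator ties everything together so the entire pipeline
can be validated end to end without patient data.

## Coordinate conventions

All geometry is in millimetres in a right-handed world frame with +z
cranial, +y anterior and +x patient-left. Angles cross the API in degrees;
lordotic (extension) angles are positive. Detector coordinates are (u, v)
in mm with the origin at the principal point, u = patient-left (frontal) /
anterior (sagittal), v = cranial; image row 1 is the most cranial row.

## The simulated biplanar environment

Each view is a point radiation source and a planar detector spanned by two
orthonormal axes; the two detector planes are mutually orthogonal. The
default geometry — source-to-image distance (SID) 1800 mm, object centered
at source-to-object distance (SOD) 1400 mm, 0.5 mm detector sampling — is
an explicit configuration value, overridable in the environment JSON,
because clinical acquisition geometry varies and should come from the
radiograph calibration. Central projection of a point follows similar
triangles (magnification SID/SOD at the object plane); an orthographic
mode exists because parallel projection admits exact closed-form test
values.

Silhouette contours are computed by rasterizing the projected footprint of
the mesh at a chosen resolution and tracing the 0.5-level boundary with
marching squares (`grDevices::contourLines`), rather than by walking
silhouette edges of the mesh graph. Rasterization is robust to
self-occlusion and multi-component meshes, and its single resolution
parameter bounds the boundary error by half a pixel. Target contours for
the synthetic experiments are derived at 0.25 mm; the sphere/box analytic
checks in the test suite verify 2% area agreement as resolution shrinks.

## Registration

The registration follows four steps: placement of the X-ray environment
(done once per case, `place_environment()`), a coarse per-vertebra initial
pose (`initialize_pose()`), target contour selection (silhouettes, partial
silhouettes, or gradient-snapped contours), and automatic contour-based
refinement (`register_vertebra()`).

`initialize_pose()` stands in for the manual vertebra alignment a user
performs in front of the viewports. It triangulates the target-contour
centroids of the two views into a 3D position (linear least squares on the
central-projection equations), aligns the 2D principal axes of the
projected silhouette with those of the target in each view, and finishes
with a coarse 1-D search over each view's in-plane rotation scored by mean
contour distance. The principal-axis step is skipped, with a warning, when
the outline is near-isotropic (minor/major eigenvalue ratio above 0.8),
because the axis direction is then not identifiable — the 1-D search still
resolves the tilt. On full silhouette targets this lands within about
1 degree / 0.5 mm of the truth; its contract in the tests is 5 degrees /
2 mm.

`register_vertebra()` is an iterative closest-point scheme specialized to
silhouettes. Each iteration:

1. extracts the occluding rim of the posed mesh with respect to each
   source (mesh edges whose adjacent faces face opposite ways from the
   source), sampled every 0.5 mm;
2. matches every densified target sample (0.5 mm) to its nearest projected
   rim point, discarding pairs farther than the 10 mm correspondence cap;
3. updates the pose by a damped Gauss-Newton step on a six-parameter
   increment (axis-angle about the correspondence centroid plus
   translation), with residuals differentiated numerically and the step
   accepted only if it does not increase the matched cost (Levenberg-style
   damping otherwise);
4. stops when the pooled RMS residual changes by less than 5e-4 mm or
   after 150 iterations.

Correspondences run from target samples to the projected silhouette, not
the reverse, because targets may deliberately cover only the well-defined
edges (vertebral body, proximal processes) while the projected silhouette
is always complete. Both views are weighted equally by default; the
weights are exposed because frontal and sagittal contour quality differ in
practice, and per-view residuals are reported separately so that
inconsistent (non-simultaneous) biplanar acquisitions remain visible
rather than silently averaged. The two views are optimized simultaneously
in one pooled least-squares problem.

Two numerical choices deserve a note. Rotations are stored as matrices and
re-projected onto SO(3) by SVD after every update, which prevents drift
over many iterations; increments are parameterized as axis-angle vectors,
which is singularity-free for the small updates the refinement needs.
Second, ICP on nearly symmetric outlines can stall in a shallow side
basin; when the final RMS residual exceeds 0.5 mm the solver deterministically
retries from up to three jittered starts (5 degrees / 5 mm, seeded) and
keeps the best basin. The per-step costs are recorded so the
non-increasing-cost property is testable per run.

The capture range is finite: from a 45-degree initial error the solver
either fails to converge or reports a residual far above the rasterization
floor — it does not silently succeed. This is the documented behavior, not
a defect; the method refines a coarse alignment, it does not search
globally.

## Contour model

Target contours are polylines in detector mm. `snap_contour()` emulates
gradient-attracted contouring: the control polyline (Catmull-Rom spline or
straight segments) is densified and every sample moves along its local
normal to the position of maximum Gaussian-derivative gradient magnitude
(sigma = 1 px) within the search window, staying put when no gradient
exceeds 10% of the image maximum — so drawn lines survive in flat regions.
These two constants are conventional edge-detection defaults, exposed as
arguments; the attraction model of the commercial contouring tool this
emulates is proprietary and unpublished, so this component is an explicit
stand-in and the validation experiments use exact silhouette-derived
targets instead.

Partial target selection is emulated by `partial_silhouette()`, which
keeps seeded contiguous arcs of the silhouette (three arcs totalling 40%
in the validation variant, mimicking corpus-edge-plus-process selections).
With partial contours the experiment initializes from the supine poses
rather than from the contours, mirroring the real workflow where manual
alignment precedes contour selection and a centroid estimate from a
fraction of a silhouette would be structurally biased.

## Measurement on midsagittal sections

The midsagittal plane has the left-right axis as its normal and passes
through the midpoint between the extreme left and right vertebral-body
vertices. `section_image()` rasterizes the cut for inspection and export;
angle measurement runs on the section geometry itself (the intersection
segments of the body faces with the plane), which avoids re-reading a
raster. Endplate lines are least-squares fits: the endplate point set is
defined as body-region faces whose outward normals lie within 30 degrees
of the vertebra's cranio-caudal axis — an explicit geometric rule standing
in for the human reading of a radiograph. Intersegmental angles use the
adjacent-endplate convention (caudal endplate of the upper vs cranial
endplate of the lower vertebra); whether the reference measurements used
adjacent endplates or mid-body axes is not stated in the literature the
bounds come from, so the convention is fixed here and stated once. LL is
cranial-L1 vs cranial-S1. The mesh-based and section-based routes agree
within 0.5 degrees on the synthetic models, and both are invariant to
whole-body rigid motion within 0.2 degrees.

## Agreement metrics

* **Dice similarity index**, `2|X∩Y| / (|X|+|Y|)`, on voxel masks. Meshes
  are voxelized at 0.6 mm by default, mirroring a typical CT
  reconstruction grid; masks to be compared share one grid. Voxelization
  marks voxel centers inside the (possibly multi-component) closed mesh by
  column-sweep ray parity.
* **Metro-style mean surface distance**: the one-sided area-weighted mean
  of exact point-to-triangle distances, estimated by stratified
  per-triangle sampling proportional to area (default 10 samples/mm²; the
  reproducibility batch uses 0.5/mm², where the estimate is already
  converged to well under 1%). The symmetric variant takes the larger of
  the two one-sided values. The maximum (Hausdorff) variant is provided
  separately.
* **ICC**: two-way mixed-effects, absolute agreement, in the
  single-measurement (A,1) and mean-of-k (A,k) forms, with F-based 95%
  confidence intervals computed from the ANOVA mean squares. The
  implementation is checked against an independent reference
  implementation on a frozen worked example to 1e-3, and against
  variance-component ground truth in simulation. Zero between-case
  variance is an error (the coefficient is undefined), as are missing
  cells.

## The synthetic spine generator

Vertebrae are simplified parametric shapes: a vertebral body extruded from
a superelliptic (rounded-box) cross-section with planar cranial and caudal
endplates whose dihedral equals the wedge angle, plus box-shaped posterior
elements (arch, transverse processes, spinous process). The sacrum carries
a posteriorly angled caudal block whose anterior-superior ridge plays the
role of the promontory edge — without it the sacral sagittal outline is
nearly rotationally symmetric and its pose is poorly identifiable, which
is an artifact a real sacrum does not have. A seeded low-order Fourier
perturbation of the body cross-section (1% amplitude) makes cases
geometrically distinct while preserving the mirror symmetry and planar
endplates that the measurement oracles rely on. Default dimensions are
typical adult lumbar values (bodies 42-55 mm wide, 27-34 mm tall, wedges
1-14 degrees).

Spines are stacked caudal to cranial with pure left-right-axis
intersegmental rotations and pure translation disc gaps (10 mm): the
emulated cohort explicitly excludes severe coronal malalignment, so
sagittal-plane-only deformity is the intended regime. The LL implied by a
plan is the sum of its five disc angles plus the five lumbar body wedges;
the generator invariant — planned vs measured angles agree within
0.2 degrees — closes the loop between simulation and measurement and is
tested over random plans.

The default plans put standing LL at 50.6 degrees and supine LL at
45.0 degrees, a 5.6-degree supine-to-standing gain at the scale reported
for degenerative cohorts. The validation experiment draws per-case
standing plans by jittering the base segment angles by ±3 degrees, and
derives the supine configuration by independent per-vertebra perturbations
within ±10 degrees (sagittal rotation) and ±10 mm (translation) — the
published accuracy bounds were established under supine-to-standing pose
differences of that order.

What the generator deliberately does **not** emulate: real radiographic
intensity (attenuation, scatter, beam hardening — silhouettes are binary
or blurred), anatomical realism beyond projected edges, coronal/axial
deformity, disc geometry, and inter-view posture differences from
non-simultaneous acquisition. Passing the synthetic suite therefore
demonstrates the correctness and precision of the geometry, optimization
and measurement chain under known ground truth; it does not measure
contour-selection difficulty on real radiographs, which the reference
accuracy bounds absorb through human raters.

## Validation experiment and problem sizes

`run_validation_experiment()` generates seeded cases, renders the standing
silhouette targets, registers the supine meshes
(`initialize_pose()` + `register_vertebra()`, with a seeded ±2 degree /
±2 mm initial-pose jitter so repeat runs are independent), sections the
registered model and measures its angles. The package's validation runs
use 20 cases (120 vertebrae) per batch — the batch size at which the
averaged statistics are stable to well under the acceptance margins —
with full-silhouette and 40%-partial variants, plus a repeat batch with a
different initial-pose seed for the reproducibility comparison
(`compare_runs()`: one-sided mean surface distances over the 120 vertebra
pairs, ICC of the measured LL). `registration_dice()` voxelizes each
registered vertebra against its ground-truth standing pose at 0.6 mm.
`scripts/acceptance.R` re-runs exactly this pipeline from a command-line
seed and writes the headline numbers as JSON.

Typical results under the default conditions: mean absolute intersegmental
angle error and LL error of a few hundredths of a degree with full
contours (about 0.1-0.15 degrees with 40% partial contours), repeat-run
surface distances of a few hundredths of a millimetre, Dice above 0.99,
and LL ICC indistinguishable from 1 — comfortably inside the published
accuracy envelope of the manual method the pipeline emulates (1.3 and
1.9 degrees; 96% of pairs below 1 mm; ICC 0.8), as expected for exact
synthetic contours.

## Known limitations

* The gradient-snapping contour tool is a conventional stand-in, not a
  reverse-engineered replica of any commercial implementation.
* The registration is local; starts beyond roughly 20 degrees need a new
  coarse initialization rather than more iterations.
* Angle measurement assumes recognizable planar-ish endplates; on severely
  deformed or osteophytic real anatomy the 30-degree normal-cone rule
  would need adjustment.
* DICOM handling (geometry import, anonymization) is out of scope;
  calibration enters via JSON.
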