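---
title: "Methods: measuring guided implant placement accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring guided implant placement accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implacc)
```

## The measurement problem

In guided implant surgery a clinician plans implant positions virtually,
prints a drilling guide, places the implants through it, and then asks how
far the achieved positions are from the plan. The standard accuracy
vocabulary reduces each planned/placed implant pair to three numbers:

* **Coronal deviation (A)** — the Euclidean distance between the planned
  and achieved platform (coronal) centres, in mm:
  \(A = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}\) at the coronal
  centre.
* **Apical deviation (B)** — the same distance at the implant apex.
* **Angular deviation** — the unsigned 3D angle between the planned and
  achieved long axes, in degrees.

`implacc` computes these from triangle meshes (STL, the lingua franca of
dental CAD), runs the two-group comparison used in bench studies of guide
systems (screw-retained versus mucosa-supported guides), and ships a
synthetic study generator so that the entire pipeline can be exercised and
calibrated without any physical models.

## From mesh to pose

An STL file carries no semantics, so the implant pose — coronal centre,
apical centre, unit long axis — must be recovered from the geometry. For
the near-cylindrical meshes of dummy implants we use:

* **Axis**: the first principal component of the vertex cloud, vertices
  equally weighted. This is deterministic and exact for symmetric
  cylinders; a cylinder least-squares fit would refine it for heavily
  distorted meshes but is unnecessary for CAD exports. Meshes whose first
  two principal extents differ by less than a factor of 1.2 are rejected
  as axis-ambiguous (a sphere has no long axis).
* **End centres**: the centroid of all vertices whose axial coordinate
  lies within `slab = 0.2` mm of each extreme. "Centre of the coronal
  aspect" has no canonical operational definition for a mesh; an end-slab
  centroid is robust to triangulation density and exact for symmetric end
  rings. With typical dental-CAD tessellations (0.1–0.5 mm edge lengths)
  the 0.2 mm default captures the full end ring; it is a configurable
  parameter of `pose_from_mesh()`.
* **Orientation**: principal components are sign-ambiguous, so
  `pose_from_mesh()` requires an `orientation_hint`, an approximate
  coronal-to-apical direction. The batch pipeline passes the planned
  implant's axis as the hint for the post-placement mesh, which makes a
  180° flip — and hence a corrupted angle metric — impossible as long as
  the true angular error is below 84° (the hint-rejection threshold).

The template generator `implant_template()` builds the canonical cylinder
(platform centre at the origin, axis along −z, apical centre at
`(0, 0, −length)`); every synthetic mesh in the package is a rigid
placement of this template, so discretisation is the only difference
between the pose path and the mesh path, and tests bound it below
0.05 mm / 0.1°.

## Registration

Bench workflows align the post-placement scan onto the planning frame in
CAD software; `implacc` re-implements that step.

* `kabsch_align()` is the closed-form least-squares rigid fit on point
  correspondences (SVD of the cross-covariance). Reflections are always
  rejected — anatomy cannot mirror — by forcing det = +1, so a reflected
  correspondence set yields the best proper rotation and a non-zero
  residual rather than a mirrored "fit". Collinear correspondence sets
  (second singular value below 1e−9 of the first) are refused.
* `icp_refine()` is point-to-point iterative closest point with
  brute-force nearest-vertex search (meshes here are desk-scale;
  no spatial index is needed below ~10^5 vertices), ties broken by lowest
  vertex index so runs are bit-reproducible. Each iteration re-solves
  Kabsch on the current correspondences, which makes the correspondence
  RMSD non-increasing. By default the iteration starts from a centroid
  alignment of the two vertex clouds: a raw identity start falls into
  lattice-shifted local minima once the displacement exceeds the mesh's
  vertex spacing, while after centroid alignment perturbations of at
  least ±1 mm / ±2° are recovered to machine precision on the package's
  fixture surfaces. Larger displacements need landmarks (e.g.
  fixation-screw head centres read with `read_landmarks()`), which
  `align_scan()` turns into a Kabsch initialisation.

The alignment step of a real study contributes an unknown share of the
reported deviations; like the bench workflow itself, the package cannot
separate it, and no alignment-error budget is modelled.

## Scan-body inference

Sub-gingival implants are invisible to an optical scanner; a scan body
screwed onto the implant makes the pose observable. `infer_implant_pose()`
registers a library template onto the scanned body (Kabsch on landmarks if
given, then ICP) and composes the result with the library's
template-to-implant offset. Two design points:

* The packaged template (`scan_body_template()`) is a cylinder with one
  planed face — rotationally asymmetric for exactly the reason real scan
  bodies are: rotation about the implant axis must be observable. It is a
  synthetic stand-in, not any manufacturer's geometry.
* A registration RMSD above 0.15 mm flags the result (`poor_fit`) but
  does not discard it, and a scan in which fewer than half the template
  vertices find a counterpart within 0.3 mm is rejected outright as not
  covering the body.

## The statistical comparison

`build_reports()` reproduces the SPSS-style analysis bench studies
publish: per metric, group summaries (n, mean, sample SD, SEM), a Levene
variance screen, and an independent-samples t table.

* **Levene's test** uses the one-way ANOVA F on absolute deviations from
  the *group mean* — the SPSS default. (`center = "median"` gives the
  Brown–Forsythe variant.)
* **Both t rows** — pooled-variance Student and unpooled Welch with
  Welch–Satterthwaite df — are always computed and reported, as an SPSS
  table does, regardless of the Levene outcome. p-values are two-sided;
  95% CIs use the corresponding t quantile.
* **Rounding** happens only at the output boundary: records are stored at
  full precision and the report writers round to 2 decimals to match the
  published table convention. Note that statistics recomputed from a
  table that was itself rounded to 2 decimals can differ in the last
  printed digit from statistics computed on the unrounded raw
  measurements; tests in this package freeze both what the packaged table
  actually yields and what its source publication printed.

**Non-independence.** Four implants share one seated guide, so
per-implant observations are clustered within models, and a t-test that
treats 20 implants as 20 independent observations is anticonservative in
the presence of a shared guide-seating error. The packaged analysis
replicates the published practice (t-tests on per-implant values) rather
than fitting a mixed model; the type-I-error calibration in the test
suite therefore uses a null error model whose guide-level components are
zero, so that observations really are i.i.d. and the test's nominal
calibration is what is measured. A block-level random effect would be the
principled extension and the manifest retains the block structure needed
to fit one.

## The synthetic study generator

`generate_study()` emulates the bench design: two methods, five mandible
models each by default, four implants per model at parallel
interforaminal positions on a 15 mm arc, 4.0 mm × 10.0 mm cylinders. The
error model is deliberately two-level, mirroring the physical mechanism:

| parameter | unit | acts on | screw-guide default | mucosa-guide default |
|---|---|---|---|---|
| `guide_translation_sd` | mm/axis | whole model (shared) | 0.18 | 0.72 |
| `guide_rotation_sd` | degrees | whole model (shared) | 1.3 | 2.4 |
| `implant_translation_sd` | mm/axis | each implant | 0.18 | 0.20 |
| `implant_rotation_sd` | degrees | each implant | 2.7 | 3.5 |
| `depth_bias` | mm | each implant, along its axis | 0 | 0 |

Rotations act about a uniformly random axis with angle `|N(0, sd)|`: the
guide rotation about the centroid of the planned platform centres (where
the guide seats), the per-implant rotation about that implant's coronal
centre. The defaults were calibrated once, semi-analytically, so that the
expected coronal and angular group means bracket the packaged study's
group statistics (≈0.44/1.23 mm coronal, ≈2.0/2.9° angular); they are
illustrative of the two guide concepts — comparable small guide and
drilling errors for the screw-retained guide, a dominant shared seating
error for the mucosa-supported one — not estimates of any physical
system. `depth_bias` defaults to zero because the bench data gives no
basis for a systematic sinking term; it exists as a knob because
mucosa-supported guides are widely suspected of one.

Because the per-implant rotation pivots at the coronal centre, apical
deviation in this model is always at least as large as coronal deviation.
Real studies sometimes observe the opposite (the osteotomy constrains the
apex); emulating that would require pivoting at the apex, a one-line
change a user can make by post-transforming poses, but the packaged model
keeps the single documented pivot.

**Expected values without simulation.** `expected_deviations()` computes
the model-implied expected A, B and angle per position. The rotations are
linearised (displacement `θ·(u × r)` at lever arm `r`), but the resulting
displacement is *not* Gaussian — its radial law is a folded normal times
a uniform-axis factor — and a Gaussian-covariance approximation misstates
the expected angle by roughly 12%. Instead the expectation uses the exact
closed-form characteristic function of each term
(`E cos(θ u·b) = √(π/2)·erf(x/√2)/x` at `x = sd·|b|`) and evaluates
`E‖X‖ = π⁻² ∫ (1 − Re φ_X(k))/‖k‖⁴ d³k` by Gauss–Legendre quadrature
(20-point sphere × 120-point mapped radial grid; the angle needs only a
single 400-point radial integral). Unit tests pin this machinery against
closed forms (chi distribution, single-rotation mean) and a 2×10⁵-sample
Monte Carlo. Parameter recovery — simulated group means matching these
expectations within 10% at 50 models per method — is the package's
substitute for bench-data equality, which a stochastic generator cannot
and should not reproduce cell by cell.

What the generator does *not* emulate: scanner noise and mesh artefacts
(vertex jitter is available separately in the test helpers), mucosal
compression during seating, drill deflection within the sleeve, CBCT
voxelisation, or any registration error (planned and placed meshes are
written in one common frame). Passing tests therefore demonstrate the
correctness of the measurement and statistics chain, not the clinical
accuracy of any guide system.

## Numerical conventions and tolerances

* Units: mm and degrees throughout; STL is unitless and read as mm.
  Coordinates are right-handed; the canonical implant frame has the
  platform at the origin and the apex at −z.
* Deviations are signed placed − planned; only magnitudes are reported in
  the published-table layout.
* Rotation matrices are validated to 1e−7 (orthonormality and det = +1);
  rigid-transform composition/inversion closes to 1e−9 in tests.
* STL reading welds vertices that agree to 1e−6 mm and drops unreferenced
  vertices and degenerate faces; both binary and ASCII dialects are
  read (auto-detected) and written (ASCII by default, for diff-ability).
* Mesh discretisation: 64 segments reproduce the closed-form cylinder
  area within 1%; generated studies default to 32 and the heavier test
  studies use 16–24, where end-centroid symmetry still makes the pose
  path exact to ~1e−9.
* Problem sizes in the test suite are chosen to keep the full suite
  around two minutes: 100-case property loops for geometry and
  registration, a 50-model-per-method recovery study, and 10⁴ replicate
  t-tests for type-I calibration.

## Known limitations

* Point-to-point ICP with centroid initialisation handles the
  small-perturbation refinement regime; large unknown displacements
  require landmarks. No trimmed/point-to-plane variants are implemented.
* The pose extractor assumes near-cylindrical implants; threaded or
  conical geometries will bias the end-slab centroids slightly (the
  length sanity check warns at 2% disagreement).
* The statistics layer replicates the published two-sample analysis; it
  does not model the block structure (see above).
* Mesh repair is limited to dropping degenerate faces; self-intersecting
  or non-manifold scans are accepted as vertex clouds.
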