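---
title: "Methods: stereo reconstruction and circumnutation kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo reconstruction and circumnutation kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circumnut)
options(circumnut.verbose = FALSE)
```

`circumnut` implements a complete measurement chain for circumnutation — the
helical oscillation of growing plant organs — from stereo time-lapse footage
to kinematic feature tables and inter-operator reliability statistics. This
vignette is the package's own account of the models it assumes, the
parameters that matter, the numerical choices made where the design was
open, and what the bundled simulator does and does not establish about real
data.

## Camera model and triangulation

Each camera is a calibrated pinhole with Brown–Conrady distortion. A world
point (mm) is taken into the camera frame by `p_cam = R p + t`,
perspective-divided to normalized coordinates, distorted with three radial
(`k1, k2, k3`) and two tangential (`p1, p2`) coefficients, and mapped to
pixels by `(fx, fy, cx, cy, skew)`. The package does **not** estimate these
parameters: calibration from chessboard images is a solved problem with
excellent standard tooling, and the interesting analysis lies downstream.
Rig parameter files (YAML; see `inst/extdata/example_rig.yaml`) are inputs.
When a rig file stores a rotation at limited precision, the reader projects
it onto the nearest proper rotation (SVD) provided it is orthonormal to
1e-5; anything worse is rejected.

Undistortion inverts the distortion polynomial by damped fixed-point
iteration on normalized coordinates — at most 50 sweeps, convergence at
1e-10 normalized units. For lenses of moderate distortion (|k1| ≲ 0.3) the
distort–undistort round trip closes to well below 1e-6 px; non-convergence
raises an error carrying the residual rather than returning a silently bad
point.

Triangulation is a two-view homogeneous direct linear transform, chosen over
the midpoint method for its standard least-squares formulation, and made
numerically honest in two ways:

* it operates in **normalized camera coordinates** (intrinsics inverted
  first), and the 4×4 system's columns are equilibrated — otherwise the
  millimetre-scale coordinate columns dwarf the homogeneous column and the
  algebraic minimum can sit tens of millimetres from the geometric one
  under pixel noise;
* rows are **iteratively reweighted by the current projective depths**
  (at most 10 sweeps, relative tolerance 1e-12), so the algebraic residual
  converges to the geometric reprojection error. A practical consequence,
  verified in the tests: applying one rigid transform to rig and points
  changes residuals by ~1e-4 px instead of tens of px.

Near-parallel rays are flagged per point (`degenerate` attribute) when the
ratio of the largest to the third-largest singular value exceeds 1e8; the
smallest singular value is the fit residual and is deliberately not used as
a conditioning measure. A zero-baseline rig is rejected at construction.
Mean reprojection error (average of the two per-view pixel distances) is
exposed as the standard quality gate; observations above about 1 px deserve
suspicion.

## Landmark tracking

Tracking is the classical iterative pyramidal Lucas–Kanade point tracker,
chained frame to frame from user-placed seeds. Defaults follow the common
practice for this footage: an 11×11 centred window (the nominal "10 by 10"
search window made odd so it can be centred), at most 30 iterations per
pyramid level, convergence at 0.01 px. A requested pyramid depth is capped
at `floor(log2(min(H, W)/window))` — halving an image 20 times degenerates
below any usable window, so the effective depth (3 for typical full-HD
frames at the default window) is logged alongside the request. The spatial
gradient matrix is tested for singularity; a singular window, or a window
that leaves the image, marks the landmark `lost`, and loss is absorbing
until a correction re-seeds it. Corrections — the file-based replacement for
an interactive GUI loop — overwrite the position at their frame exactly
(status `corrected`) and tracking resumes from there. RGB frames are
converted to grayscale by luminance (0.299 R + 0.587 G + 0.114 B), which is
logged, since acquisition systems that switch to infrared at night deliver
mixed-mode footage.

## Plant frame, α angle, segmentation

The plant frame maps a stable stem point (first internode) to the origin and
a second point up the stem (second internode) to the positive y-axis. Two
points leave the rotation about y undetermined; it is fixed by sending the
projection of the world x-axis onto the plane perpendicular to the plant
axis to the plant x-axis (world z-axis as fallback when the plant axis is
parallel to world x). This is deterministic and keeps the horizontal plane
view-aligned; all plant-frame transforms are exact isometries.

The α angle of each frame pair is the four-quadrant angle of the planar
(dx, dz) movement component, wrapped to [0, 2π). A stationary frame pair
inherits the previous α (0 at the start) so pauses do not inject spurious
angles. For a circling organ α is a sawtooth; a **centred 5-sample moving
average on the wrapped values** (window shrinking symmetrically at the
edges, so the first and last angles are averaged over whatever centred
window fits) suppresses sample noise while preserving the wrap
discontinuities — the signal is deliberately *not* unwrapped, because the
segmentation uses the wraps as cycle boundaries. Circumnutations are the
spans between consecutive local maxima of the smoothed α; samples before
the first and after the last maximum belong to no circumnutation, so n
detected maxima yield n − 1 circumnutations.

Peak picking takes strict local maxima (plateaus yield their last index)
filtered by topographic prominence with a default threshold of **π/2 rad**.
The threshold is a package choice: noise-free sawtooths have 2π-high teeth,
so π/2 rejects jitter-induced micro-peaks while passing any genuine wrap;
setting `min_prominence = 0` recovers literal every-local-maximum
behaviour for users who want it.

## Features

All internal computation is in mm and seconds; reported speeds default to
mm/h (the natural scale of circumnutation — tens of mm/h) and are
configurable to mm/s.

* **Path length** is the 3D chord sum over the circumnutation, reported in
  the tables as `line_integral` (its conventional column name).
* **Centre vs centroid**: the centre is the mean of the trajectory points
  in X–Z; the centroid is the mean of the filled cells after rasterizing
  the closed planar loop. Rasterization uses an **even–odd fill** on a grid
  of 0.1 mm cells, so self-intersecting loops still enclose a defined
  region; area is the filled-cell count times the cell area, and the count
  is logged. 0.1 mm is well below any real orbit scale, making the area
  resolution-convergent (a 10 mm-radius circle rasterizes to within 2% of
  π r²); collinear degenerate loops get area 0, the vertex mean as
  centroid, and a warning.
* **Centre/centroid speed**: centres exist once per circumnutation, so
  "speed" is implemented as the planar displacement between consecutive
  circumnutations' centres divided by the time between their midpoints,
  absent for the last circumnutation. The underlying definition is
  genuinely ambiguous in per-frame terms; this interpretation is the
  package's documented choice, not an assertion about anyone else's.
* **Main axis** is the exact longest planar chord (computed on the convex
  hull).
* **Direction** sums the signed turning angles between consecutive planar
  movement vectors (each wrapped to (−π, π], counterclockwise positive
  viewed from +y, zero-length vectors skipped): within 2π ± 1.2 rad is
  counterclockwise, within −2π ± 1.2 clockwise, anything else unassigned.
  The 1.2 rad tolerance is kept as the conventional default and exposed as
  a parameter. A closed convex loop's turning sum is ±2π to machine
  precision only when the movement-vector sequence itself closes (the
  wrap-around sample is included) — the test fixtures do exactly that.
* **Stimulus features** fold the main-axis/stimulus-axis angle into
  [0°, 90°], treating both lines as undirected; a stimulus at the plant
  origin leaves the angle undefined (warning, absent value). The minimum
  stimulus distance is 3D for a point stimulus and planar for a vertical
  pole; a pole is the default model since supports are typically upright
  and a planar distance needs no height coordinate.

## Reliability statistics

Operators are compared per frame (3D distances, histogram at 1 mm bins),
per axis (Pearson correlation), and per feature with **ICC(A,1)** — the
single-rater, absolute-agreement, two-way random-effects intraclass
correlation. From the two-way mean squares (subjects MSR, raters MSC,
residual MSE):

$$\mathrm{ICC}(A,1) = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)}$$

Absolute agreement (rather than consistency) is the right cell of the ICC
taxonomy here because a constant bias between operators *should* count as
disagreement — duplicated raters give exactly 1, a large one-rater shift
drives the coefficient toward 0 even when the correlation is perfect. The
null hypothesis ICC = 0 is tested with `F = MSR/MSE` on `(n−1, n(k−1))`
degrees of freedom; conventions differ on the error df for this test (the
exact two-way null distribution uses `(n−1)(k−1)`), and the implemented
convention is stated here so no reader needs to guess. For `k = 2` raters
the difference is a handful of denominator df and does not move any
conclusion at realistic n.

Feature tables from two operators are aligned by circumnutation index after
independent segmentation; counts differing by up to 20% are trimmed to the
common length (logged), larger mismatches raise an error demanding manual
alignment rather than silently discarding data.

## The simulator: what it emulates, and what passing tests do not show

`gen_trajectory()` produces an elliptical helix: semi-axes `a, b` (default
10 mm — a typical pea-shoot orbit), mean period `T` (3600 s), vertical
growth (2 mm/h), optional linear drift of the orbit centre, a handedness
schedule with phase-continuous switches, and iid Gaussian positional noise.
Sampling defaults to `dt = 180 s ≈` the 0.0056 Hz time-lapse interval the
package targets; `dt > T/8` is rejected as undersampled. Two optional
jitters make cycles individual: per-cycle Gaussian period jitter
(`period_sd_s`, truncated to [T/2, 2T]) and per-cycle amplitude scaling
(`amp_sd_frac`, truncated to [0.5, 1.5]) interpolated linearly within each
cycle so the path stays continuous. Both default to 0 — a perfectly
rhythmic plant — but the reliability analyses use `period_sd_s = 900 s`
and `amp_sd_frac = 0.15` over 30 cycles, because an intraclass correlation
is *defined over* between-circumnutation variance: with identical cycles
the subject variance is zero and ICC is meaningless, and real plants vary
their cycles far more than these settings do.

`default_rig()` mimics a growth-chamber installation: two full-HD cameras
300 mm apart, converging on the plant from 800 mm, focal length 2000 px
(about a 6 mm lens on a 1/2.8" sensor), mild radial and tangential
distortion. At this geometry 0.5 px of observation noise resolves a point
to under 1 mm RMS, which is the regime the reconstruction is meant for.
`render_stack()` renders a Gaussian blob per frame over optional background
noise; `gen_rater_pair()` adds independent per-coordinate Gaussian noise to
emulate two operators.

Limits of what the simulator can certify:

* **Operator error is modelled as independent** between raters. Real
  operators track the *same* footage with the same algorithm, so their
  errors are strongly correlated and their feature ICCs are
  correspondingly higher than the independent-noise model predicts —
  especially for extreme-value features (min/max speed) and the main-axis
  angle, which are intrinsically sensitive to uncorrelated noise. The
  package's agreement tests therefore assert strong ICCs for the
  distance-robust features (duration, main axis, area, mean speed) and a
  median-level bar across the full table, not uniformly near-1 values.
* Noise is iid per coordinate with no temporal correlation; drift,
  tremor-like correlated noise, lighting changes, occlusion and blob
  appearance changes are not modelled, so the tracker results bound
  performance on clean footage only.
* The simulated organ is a single point; multi-point organ-axis
  reconstruction is out of scope.

## Problem sizes and determinism

All generators are bit-reproducible under a fixed seed. The test suite and
the validation script run on deliberately compact problems — 1000-point
stereo clouds, 10–30 simulated cycles at 180 s sampling, 100-frame rendered
stacks, 200 replicate 500×2 rating matrices — sizes at which every
closed-form tolerance in the tests is already comfortably resolved.

## Known limitations

* Calibration estimation, >2-camera fusion, bundle adjustment and
  rolling-shutter models are out of scope; the rig file is trusted.
* Segmentation assumes the plant frame's y-axis is the nutation axis;
  movements whose rotation plane tilts far from horizontal will smear the
  α sawtooth and may need a different projection plane.
* The first and last partial cycles of a recording are never assigned to a
  circumnutation by construction.
* Feature tables use the conventional column identifiers
  (`duration_circumnutation`, `line_integral`, ...), so downstream scripts
  written against that convention work unchanged.
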