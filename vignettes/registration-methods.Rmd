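---
title: "Rigid 2D/3D coronary centerline registration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid 2D/3D coronary centerline registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(vesselreg)
```

## The problem

During percutaneous coronary intervention the operator works from 2D X-ray
angiograms (XA), which carry no depth and only show vessels filled with
contrast at that instant. A preoperative CT angiography (CTA) scan provides
the full 3D vessel anatomy. Overlaying the 3D coronary tree on the live 2D
frame gives the operator both at once — provided the two can be aligned
quickly and robustly. `vesselreg` performs that alignment as a rigid
6-parameter pose search: the 3D centerline tree (polylines in patient mm)
is projected through the C-arm's acquisition geometry and moved until it
falls onto the 2D centerline extracted from the XA frame. Centerline
extraction itself is out of scope: both centerlines are inputs.

The pipeline has five parts, each exposed as ordinary functions:

1. **Cardiac phase matching** (`detect_r_peaks()`, `frame_phase()`,
   `select_candidate_frames()`): the CTA is reconstructed at a known
   fraction of the R-R interval; the XA frames whose ECG phase matches are
   the candidates to register against.
2. **Importance weighting** (`classify_subbranches()`,
   `assign_importance()`): every 3D centerline point receives an anatomical
   weight so that reliable proximal anatomy dominates the similarity.
3. **Projection and initial alignment** (`project_points()`,
   `initial_translation()`): the C-arm metadata fixes rotation and
   magnification; the missing translation is estimated by matching
   margin-expanded bounding boxes.
4. **Similarity** (`build_local_distance_map()`, `aadd()`): a capped local
   distance map makes point-to-curve distance a table lookup.
5. **Optimization** (`register_vessels()`): staged, bounded Powell search
   over the pose.

## Projection model

The C-arm is modelled as a pinhole camera, `p2d ~ K [R | t] P`. The
intrinsic matrix uses focal length `f = SID` (source-to-detector distance,
mm) and pixel densities `m = 1/spacing` (px/mm), so the detector-plane
magnification `SID/SOD` is encoded by the geometry itself and the imager
pixel spacing is used exactly as the DICOM header states it. The extrinsics
place the source at distance SOD from the isocenter along the camera axis.

No vendor-independent axis convention exists for positioner angles, so the
package fixes one and documents it: patient coordinates are x = patient
left, y = posterior, z = head; the primary angle rotates the camera about
the patient head-foot axis (RAO/LAO) and the secondary about the
left-right axis (caudal/cranial); at zero angles the source is anterior
(PA-like view). Five metadata values drive everything (positioner primary
and secondary angle, imager pixel spacing, SID, SOD), read from a JSON
sidecar by DICOM keyword — keywords rather than tag numbers, since
published tag numbers for the two positioner angles are inconsistent
across sources. Clinical exports occasionally carry a signed SID; its
absolute value is used with a warning, as a negative source-detector
distance is physically meaningless. The principal point defaults to the
image center when the header lacks one.

The pose is `(Tx, Ty, Tz)` in patient mm plus `(Rx, Ry, Rz)` in degrees,
composed `Rz Ry Rx` about the tree centroid. Any fixed proper-rotation
parameterization is equivalent at the small bounded angles involved; one
is fixed and documented. Rotating about the centroid keeps rotations from
translating the tree off-screen, which is what makes small rotation bounds
meaningful.

## Importance weighting

Coronary anatomy is weighted per SCCT-style segmentation. Main branches
(RCA, or LAD and LCX) carry importance interpolated linearly in normalized
arc length from 1.0 (proximal) to 0.1 (distal) — linear is the minimal
assumption consistent with a smooth proximal-to-distal gradient. Active
sub-branches start at their attachment's importance and decay linearly at
0.02/mm (configurable), floored at 0.1; inactive sub-branches sit at 0.1
everywhere. A sub-branch is active while the count of sub-branches in its
anatomical area (the proximal/mid/distal segment of its main-branch
attachment) stays at or below a per-segment reference count, default
(proximal 2, mid 2, distal 1); the excess is deactivated farthest from the
root first, since distal side-branch correspondence is the least reliable.
Classification runs on the 3D tree against these configurable reference
counts; comparing against the 2D image's own branch count would be the
alternative reading, and the reference counts are the hook for it. When
SCCT segment labels are absent, `label_segments()` splits each main branch
into equal arc-length thirds.

## Local distance map and AADD

The 2D centerline mask is turned into a distance field by chamfer
propagation over the 8-neighbor pixel graph with steps 1 and `sqrt(2)`,
swept forward and backward repeatedly until a fixed point — the result is
then the exact shortest chamfer-path distance, independent of scan order,
and overestimates true Euclidean distance by at most ~8.2%. Distances are
capped at `d_max`: pixels farther than the cap hold exactly `d_max`, which
both bounds the work and saturates the similarity for far-off points. One
mm-valued `d_max` (13 mm) serves as both the translation bound and the map
cap (converted to pixels by the spacing), keeping the two uses of the same
symbol consistent.

The similarity is the importance-weighted average absolute distance
difference

    AADD = (1/N) * sum_i alpha_i * D(project(pose(P_i)))

with `D` the capped map lookup in detector mm; points projecting outside
the image contribute `alpha_i * d_max`. Queries are nearest-pixel by
default; the optimizer uses bilinear interpolation (config
`query_mode`) because the interpolated field gives Brent line searches a
smoother landscape at negligible cost.

## Staged bounded optimization

Registration runs: initial translation from bounding boxes, then Powell
direction-set minimization over `(Tx, Ty, Tz)`, then over all six
parameters, each stage bounded to `|T| <= 13 mm`, `|R| <= 12 deg`
*relative to the initial pose* — the only reading under which the initial
registration restricts the search space. The bound values are the
experimentally determined thresholds reported for this procedure. Powell's
method is implemented in-package (no installed R package provides the
direction-set variant): cycling Brent line searches (`stats::optimize`)
over a direction set, replacing the direction of largest decrease with the
net displacement under the standard extrapolation test. Line searches are
restricted to the box intersection, and — belt and braces — candidates
outside the box are penalized by `d_max * (1 + excess)`, a smooth push
back inside; clamping alone would create flat regions that stall the
search. Defaults: parameter tolerance `1e-3` of each bound, relative
function tolerance `1e-4`, 200 iterations per stage, no randomness
(optional seeded restarts exist, default 0). The returned pose is never
worse than its start, and the per-stage AADD trace is non-increasing by
construction.

The bounding-box initializer matches centers (pixel offset converted to
object-plane mm through the magnification and mapped into patient axes)
and optionally depths (ratio of box diagonals through the perspective
relation `scale ~ SID / camera-z`). Center-plus-scale is the minimal
complete reading of box matching; both boxes get the same margin `e`
(default 10 px), which therefore cancels in the estimate but reflects that
each box is padded against residual cardiac deformation.

## Cardiac phase matching

R peaks are detected Pan-Tompkins-style: zero-phase 5-15 Hz Butterworth
band-pass, squaring, local maxima above an adaptive threshold with a
refractory spacing (default 0.3 s) that suppresses T waves. Frame phase is
the fractional position inside its R-R interval; candidate frames match
the CTA reconstruction phase within a circular tolerance (default 0.05,
about one frame at 15 fps and 75 bpm; circular so end-diastolic phases
near the 0/1 boundary match correctly). When several frames match, the one
whose registration error is smallest wins (`select_best_frame()`); whether
to run the full registration per candidate or only the cheaper initial
stage is the caller's trade-off — both are possible since the functions
compose.

## The synthetic generator

`generate_vessel_tree()` builds coronary-like trees: one smooth main
branch of 80-150 mm (random-walk control points with ~18 deg turning,
spline-interpolated; the left side gets an LCX splitting off near the root
as a left-main simplification), 2-6 sub-branches of 15-40 mm, SCCT-style
segment thirds, ten markers, resampled at 0.5 mm — below typical CTA slice
thickness, so resampling invents no information. `generate_case()` draws
the C-arm geometry uniformly from published clinical acquisition ranges
(primary angle -37.4..57.5 deg, secondary -43.5..45 deg, SID 949-1208 mm,
SOD 649-810 mm, spacing 0.244-0.293 mm/px, 512x512), draws a ground-truth
pose uniformly within a chosen fraction of the search bounds, and renders
the truly-posed tree into a binary mask; the returned tree carries the
unperturbed pose, so the drawn pose is the recovery target. Steep
geometries (SID/SOD up to ~1.86) leave a ~67 mm object-plane field of
view, so the tree is shrunk about its centroid when its zero-pose
projection would exceed 70% of the detector. `generate_ecg()` produces a
sum-of-Gaussians PQRST waveform with ±3% beat-to-beat jitter and white
noise at a requested SNR, returning the exact R-peak times.

What the generator does *not* emulate matters for interpreting green
tests: the 2D mask is rendered from the same tree that is registered, so —
apart from an optional spurious clutter branch and optional raster
jitter — the 2D and 3D centerlines agree perfectly at the true pose and
the similarity has an exact zero there. Real XA/CTA pairs never do:
segmentations differ, vessels foreshorten and deform non-rigidly within
the matched phase, and contrast fills incompletely. Passing recovery tests
therefore demonstrates the correctness of the geometry, similarity and
optimizer, not clinical-grade accuracy.

This self-consistency has one concrete consequence worth stating plainly.
The anatomical weighting exists to resist disagreements between the two
centerlines; but in a synthetic case whose only disagreement is an
injected spurious 2D branch, the true pose still scores exactly zero for
weighted and unweighted objectives alike, so down-weighting points can
only discard constraints. In our ablations the uniform-weight variant is
as accurate or slightly more accurate in most seeds, and decoy-capture
events — where weighting should help — are rare and nearly symmetric,
because a low-weight point can also drift onto a decoy at almost no
weighted cost. Demonstrating the weighting's benefit requires mismatch
with no zero-residual pose (e.g. branches present in only one modality),
which is real-data behavior the generator deliberately does not fabricate
beyond the single clutter branch. The weighting is implemented and tested
for its stated contract (assignment rules, monotonicity, bounds); its
robustness advantage is a claim about clinical data that desk-scale
synthetic tests cannot establish.

## Numerical choices and degenerate inputs

* Resampling leaves a branch untouched when it already conforms to the
  step (spacing at or below the step and no over-resolution), making the
  operation exactly idempotent; a step longer than a branch collapses it
  to its endpoints.
* The distance map caps by `min(d, d_max)` computed at the chamfer fixed
  point, so capped values are exact, not path-truncated.
* Empty masks, empty point sets, flat ECG traces, degenerate (zero-area)
  bounding boxes and points behind the X-ray source are explicit errors
  or warnings, not silent propagation.
* Equal-objective ties: `select_best_frame()` prefers the earlier frame;
  the optimizer keeps the incumbent unless strictly improved.
* All randomness is seeded through function arguments; generators restore
  the caller's RNG state.

## Test problem sizes

The suite exercises 20-seed batches for pose recovery (perturbations at
2/3 of the bounds), the weighting ablation, R-peak detection at 10 dB SNR,
and 64x64 distance-map oracle comparisons against an independent Dijkstra
shortest-path route; micro-examples for AADD and marker ADD are
hand-computed. These sizes keep the full suite in the minutes range on one
CPU while leaving every property statistically meaningful; the same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Rigid-only: no thin-plate-spline or other non-rigid refinement, and no
  multi-frame (2D+t) tracking.
* Centerline extraction from CTA volumes or XA images is out of scope.
* Geometry metadata is read from JSON sidecars of DICOM keywords, not raw
  DICOM files.
* Object-plane error reporting divides detector mm by `SID/SOD`; whether a
  clinical report means detector- or object-plane mm is ambiguous, so both
  are available (`plane =` argument).
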