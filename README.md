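# vesselreg

Rigid 2D/3D registration of coronary artery centerlines: aligns a
preoperative 3D centerline tree from CT angiography (CTA) with the 2D
vessel centerline of an intraoperative X-ray angiogram (XA) frame, the
overlay used to guide percutaneous coronary intervention (PCI). Both
centerlines are inputs; extracting them from images is out of scope.

## Method

The XA frame is selected by cardiac phase: R peaks are detected on the ECG
(band-pass, squaring, refractory local maxima), each frame's phase is its
fractional position in the R-R interval, and frames matching the CTA
reconstruction phase are the candidates. The C-arm acquisition metadata
(positioner primary/secondary angle, imager pixel spacing,
source-to-detector and source-to-patient distance) fixes a pinhole
projection

```
[x, y, 1]' ~ K [R | t] [X, Y, Z, 1]',   K = [[f·mx, 0, px], [0, f·my, py], [0, 0, 1]]
```

with `f = SID` and `m = 1/pixel spacing`, leaving only the patient
translation unknown; that is initialized by matching margin-expanded
bounding boxes of the projected 3D and the 2D centerlines (centers
in-plane, diagonal ratio in depth). The 2D centerline mask becomes a local
distance map by 8-neighbor chamfer propagation (steps 1 and √2) capped at
`d_max`, so the similarity — the importance-weighted average absolute
distance difference

```
AADD = (1/N) Σ αᵢ · D(project(pose(Pᵢ)))
```

— is a table lookup per projected point. The weights `αᵢ` encode coronary
anatomy: main branches (RCA, LAD, LCX) fall linearly from 1.0 proximal to
0.1 distal; active sub-branches decay from their attachment value;
inactive (surplus) sub-branches sit at 0.1. The 6-parameter rigid pose
`(Tx, Ty, Tz, Rx, Ry, Rz)` is found by staged Powell direction-set
minimization — translation first, then full rigid — with every parameter
bounded to ±13 mm / ±12° around the initial pose. Accuracy against ground
truth is reported as mean centerline, paired-marker (ADD) and bifurcation
distances in mm.

## Worked example

Generate a synthetic case (tree + C-arm geometry + ground-truth pose +
rendered 512×512 mask), register, and evaluate:

```r
library(vesselreg)

case <- generate_case(seed = 42, scale = 2/3)          # perturbation within 2/3 of bounds
tree <- case$tree |> classify_subbranches() |> assign_importance()
res  <- register_vessels(tree, case$centerline, case$geom)
res
#> <registration_result>
#>   pose: T = (-0.0776, -9.56, 1.04) mm, R = (3.53, -0.619, 3.5) deg
#>   AADD: 1.289 -> 0.4957 -> 0.04283 (initial -> translation -> rigid)
#>   3458 objective evaluations

evaluate_registration(res, tree, case$mask, case$true_pose)
#> # A tibble: 1 × 4
#>   centerline_mm marker_mm bifurcation_mm reprojection_mm
#>           <dbl>     <dbl>          <dbl>           <dbl>
#> 1        0.0926     0.161         0.0963           0.123
```

The AADD trace shows the two optimization stages each reducing the
weighted distance (mm at the detector plane); the final 0.043 mm means the
projected centerline lies essentially on the 2D centerline. The evaluation
row gives object-plane errors against the known true pose: the registered
centerline is within ~0.1 mm of ground truth, markers within 0.16 mm.
`tidy(res)` returns the six pose parameters with their bounds,
`glance(res)` a one-row summary, and `autoplot(res)` the depth-colored
overlay of the registered centerline on the mask.

A file-based pipeline (`run_pipeline()`) and a CLI
(`inst/cli/vesselreg.R` with `register`, `synth`, `eval` subcommands)
wrap the same functions for case directories
(`tree.json`, `mask.png`, `geom.json`, `ecg.csv`, `truth.json`).

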