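---
title: "Thermal point clouds from a LiDAR line scanner and a radiometric camera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal point clouds from a LiDAR line scanner and a radiometric camera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Fruit surface temperature (FST) drives heat-stress physiology in apple —
sunburn browning begins in the high 40s °C — but contact thermometry wounds
the fruit and samples a single spot. A mobile 2D LiDAR line scanner
(0.1667° angular resolution over a 180° fan, 25 Hz) paired with a
radiometric thermal camera (640 × 480 px, values already in °C) can
instead produce a *3D thermal point cloud* of a whole tree row, from which
the temperature field over every visible fruit is read off.

`thermocloud` implements the full chain:

1. **Intrinsic calibration** of the thermal camera against an actively
   heated lightbulb board (thermal cameras cannot see printed
   checkerboards).
2. **Extrinsic calibration** of the rigid rotation/translation between
   the LiDAR and camera frames.
3. **Fusion**: projecting every LiDAR point into the thermal frame and
   assigning the nearest pixel's temperature.
4. **Fruit segmentation**: per-point eigenvalue curvature and
   backscattered reflectance thresholds, Euclidean clustering, and
   per-fruit FST statistics with an east/west side label.
5. **Simulators** that generate every input with known ground truth, and
   the **metrics** (RMSE, MBE, adjusted R², detection F1) used to score
   them.

# Models and procedures

## Camera model

A pinhole camera with focal lengths $(f_x, f_y)$ and principal point
$(c_x, c_y)$ (the camera matrix $A$), plus radial $(k_1, k_2, k_3)$ and
tangential $(p_1, p_2)$ distortion: a camera-frame point $(X, Y, Z)$,
$Z>0$, is normalised to $(x, y) = (X/Z, Y/Z)$, distorted with
$r^2 = x^2 + y^2$,

$$x_d = x(1 + k_1 r^2 + k_2 r^4 + k_3 r^6) + 2 p_1 x y + p_2 (r^2 + 2x^2),$$

(similarly $y_d$), and mapped to pixels $u = f_x x_d + c_x$,
$v = f_y y_d + c_y$. Pixel origin is the top-left pixel centre, x
rightward, y downward, integer pixel centres. No thin-prism or fisheye
terms are modelled.

## Intrinsic calibration from the heated board

The board carries $m = 30$ lightbulbs in a 5 × 6 grid at 100 mm spacing
on a 0.5 × 0.6 m panel. Detection is *staged*: the image is rescaled to
8 bit over its own temperature range, a multi-threshold blob detector is
run with up to three sensitivity presets, and on failure the lower bound
of the range is raised by 5 °C and the sweep repeated (up to 4 ranges ×
3 presets = 12 attempts, after which the view is discarded, never
silently dropped). Success means *exactly* 30 blobs. Only the first
preset (20, 220, 15, 160, 230) comes from the instrument protocol; the
second and third are package defaults that widen the area band
(80–350, then 20–600 with a finer threshold step), because a blob's
pixel area varies strongly with viewing distance and incidence.

Detected blobs are sorted into canonical row-major order by projecting
onto the constellation's principal axes, splitting into rows at the
largest gaps along the minor axis, and orienting the axes by the image
axes — stable for in-plane rotations to at least ±30°.

Calibration itself is the classic planar-target scheme: per-view
homographies give a closed-form camera matrix and per-view poses, then
Levenberg–Marquardt minimises the total reprojection error
$\sum_i \sum_j \lVert o_{ij} - \hat o(A, D, R_i, t_i, O_j) \rVert^2$
over $A$, $D$ and all poses. At least three views with distinct board
orientations are required; identical poses are detected as a
rank-deficient constraint system and refused.

## Extrinsic calibration

Per scan: the assembled 3D cloud is box-cropped so the board is the
dominant plane, the plane is extracted by RANSAC (10 mm threshold,
1000 iterations, ≥500 inliers — values chosen for a board at 1–2 m with
±5 mm range noise), and the inlier extents must match the board
dimensions within ±10 % or the scan is rejected (boards cut off by the
scan window fail exactly this test). The board pose is initialised from
the downsampled inliers and refined by point-to-point ICP against a
synthetically sampled perfect board model (5 mm grid); the 30 bulb
positions follow from the pose, are paired with the sorted image blobs,
and the camera-from-LiDAR transform is solved by homography
initialisation plus Levenberg–Marquardt reprojection minimisation.
Candidates from all valid scans are compared by the cross-scan
reprojection RMSE
$\sqrt{\sum_{i}\sum_{j} \lVert m'_{ij} - m_{ij}\rVert^2 / (NM)}$;
the element-wise parameter mean is evaluated alongside and the lowest
RMSE wins.

Two implementation points deserve note, both discovered on simulated
data and both documented behaviour:

* **In-plane board orientation.** For a 0.5/0.6 aspect board the two
  in-plane covariance eigenvalues are so close that the principal axes
  swing by several degrees under small sampling perturbations (a cross
  term $C$ rotates them by $\approx \tfrac12 \arctan 2C/(\lambda_1 -
  \lambda_2)$, and the scan density of a moving line scanner is far from
  uniform). The pose initialisation therefore takes the *normal* from
  the PCA but the in-plane axes from the minimum-area enclosing
  rectangle of the plane-projected points, whose orientation is pinned
  by the board's own edges. Downsampling is done on a grid laid *in the
  board plane*, which equalises the range-dependent density.
* **Composition order.** The final pose is
  $T_{final} = T_{initial} \circ T_{corr}$ with the ICP correction
  expressed in the board frame; a directed test pins this convention.

## Fusion

Every point is transformed to the camera frame and projected through the
full distortion model. Points projecting inside the image (and in front
of the camera) take the *nearest* pixel's temperature — interpolation
would blur the blob/background and fruit/background boundaries. All
other points take the sentinel −10 °C, a value outside any plausible
orchard scene; no point is ever dropped, so downstream geometry is
unaffected by the camera's narrower field of view. Fusion is idempotent.

Occlusion is not modelled by default: a point hidden behind foliage
samples the foreground pixel, exactly as a single-view projection does.
An optional depth buffer (`zbuffer = TRUE`, 5 cm tolerance, 3 × 3 pixel
splat because LiDAR points are sparse relative to pixels; the buffer may
be built from a merged multi-view cloud) marks such points with the
sentinel instead. The orchard study pipeline enables it, because FST
averages are otherwise biased low by foliage pixels.

A moving rig sees one thermal frame per ~20 ms; `fuse_frames()` fuses
each point with the frame captured nearest to it along the travel axis,
which keeps the viewing parallax and the per-fruit pixel footprint
small. Single-frame fusion (`fuse_temperature()`) remains the primitive.

## Fruit segmentation

The two scanned sides of a row are registered by point-to-point ICP from
a platform-geometry initial estimate, with a 6 cm correspondence cap:
opposite sides only truly overlap on thin structures (leaf planes, trunk
silhouettes), and uncapped correspondences pull the front and back
canopy faces together. Stems come from a bivariate point-density
histogram (5 cm bins, trunk band 0.2–0.8 m, non-maximum suppression at
0.5 m); trees are cut as 0.45 m cylinders (half the 0.95 m planting
pitch).

Per tree, each point's $k = 30$ neighbourhood is mean-centred and its
covariance eigen-decomposed to $\lambda_1 \ge \lambda_2 \ge \lambda_3
\ge 0$; the change-of-curvature $c = \lambda_3 / (\lambda_1 + \lambda_2
+ \lambda_3)$ is rescaled per cloud to 0–100, so the scaled value
attains 0 and 100 on every non-constant cloud. Apples are the
high-curvature, high-reflectance class: candidates satisfy
$C_{th} \le C$ and $R_{th} \le R$. Thresholds come from the valley
between the two dominant modes of a kernel density estimate; sub-modes
separated only by a shallow saddle (saddle above half the lower peak,
e.g. leaf vs trunk reflectance) are merged first, and unimodal features
fall back to a percentile (25th for curvature — permissive, since the
criterion is a conjunction — and 90th for reflectance). Candidates are
grouped by single-linkage clustering at 20 mm (fruit diameter 60–80 mm
at mm-level point spacing); clusters under 30 points are discarded.
Each cluster reports its centroid, a least-squares sphere radius, FST
mean/min/max/SD over non-sentinel temperatures, height, and an
east/west label from the sign of its centroid's offset along the row
normal (exact ties go deterministically to east).

Under 5 mm range noise the curvature contrast between a 35 mm sphere and
a leaf patch nearly vanishes (the sagitta over a 15 mm neighbourhood is
~3 mm), so on the synthetic orchard the discrimination is carried mostly
by reflectance, with curvature as a weak co-filter; at lower range noise
curvature regains its power. This is a property of the method itself,
not of the implementation.

## Metrics

`regression_metrics()` reports MBE (mean of predicted − observed), RMSE,
the R² of the least-squares line of predicted on observed, and the
adjusted form $1 - (1 - R^2)(n-1)/(n-p-1)$. ("Adjusted" is the standard
reading of the coefficient-of-determination variant used for this
report shape.) `detection_f1()` uses greedy one-to-one nearest-distance
matching inside a match radius; an exhaustive-assignment oracle confirms
the greedy count on small instances. `sphere_report()` reproduces the
per-material (white barium-sulphate vs black urethane sphere) report
shape used for evaluation frames.

# The simulators, and what they do not show

All tests run against generated scenes with per-point/per-pixel ground
truth: an actively heated board observed by a moving scanner (bulb
centres near 46.3 °C on a 21.4 °C board — the fused-cloud statistics the
instrument produces), a 2 m metal evaluation tree with 15 coated
spheres, and an orchard row (trunk cylinders, leaf disks, fruit spheres
with an east/west temperature offset, default +0.5 °C east). Sensor
defaults follow the instrument: 0.1667°/180°/25 Hz scanner at 20 mm/s on
the calibration conveyor, 640 × 480 thermal frames, 5 mm range noise,
0.05 °C thermal noise. The orchard platform speed is not a published
constant; the generator uses 0.10 m/s, a typical orchard phenotyping
platform speed, and 0.1 °C fusion noise for the standard fixture. The
study fixture uses 5 trees at 0.95 m pitch, 10 fruits per tree, 50 leaf
disks per tree — sizes chosen so the full two-sided pipeline runs in a
few minutes on one core; they are stated here as the package's standard
fixture, and nothing in the code depends on them.

The generators are deterministic per seed and every emitted point and
pixel is traceable to a surface id. They do **not** emulate: emissivity
and atmospheric effects (pixels are true surface temperatures), wind
motion, beam-footprint mixing at silhouettes, multi-return LiDAR, dense
within-canopy occlusion, or georeferencing drift. Passing tests
therefore show the *algorithmic* chain is correct and self-consistent,
not that field data of arbitrary quality will reach the same accuracy.
Two systematic effects of the real method are visible even in
simulation and are left in place deliberately: nearest-pixel sampling
missamples a thin silhouette ring of every fruit (a ~0.05–0.1 °C cool
bias at the simulated pixel footprint), and fruits heavily occluded
from the scanner yield few points and may fall under the cluster-size
floor.

# Numerical choices

* Half-up rounding in the 8-bit conversion (platform-stable).
* Blob grouping across threshold slices at 10 px, minimum two supporting
  slices.
* RANSAC plane threshold 10 mm, 1000 iterations, ≥500 inliers; board
  dimension tolerance ±10 % with 0.1 %-tail-trimmed extents (oblique
  range-noise smear otherwise inflates the measured size).
* ICP: correspondence re-solve per iteration, convergence on the mean
  correspondence distance (1e−9 m board registration, 1e−7 m side
  alignment), non-convergence returns the last iterate with a warning.
* Degenerate inputs: duplicate-point neighbourhoods get curvature 0 with
  a flag; constant features are refused by name; collinear point sets
  are refused in plane and pose fits; a solver that cannot separate the
  camera parameters reports the degeneracy rather than a bogus fit.
* All randomised algorithms draw from R's RNG so callers seed them.

# Known limitations

* The extrinsic solve assumes a fixed, already-calibrated camera; no
  joint (bundle) refinement of intrinsics and extrinsics.
* Single-camera, single-return geometry; no motion-distortion model
  beyond constant platform velocity.
* The side-alignment ICP needs an initial estimate within its capture
  range; it will not rescue a grossly wrong platform pose.
* FST is reported for detected clusters only; fruits with too few
  LiDAR returns (deep occlusion) are absent rather than guessed.
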