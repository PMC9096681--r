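# thermocloud

Fruit surface temperature (FST) governs heat-stress disorders in apple —
sunburn browning starts when the skin spends minutes in the high 40s °C —
yet contact thermometry wounds the fruit and samples one point.
`thermocloud` builds **3D thermal point clouds** from a mobile 2D LiDAR
line scanner (180° fan, 0.1667° resolution, 25 Hz) and a radiometric
thermal camera (640 × 480 px, values in °C), and segments the
temperature field of every visible apple in a scanned tree row.

The package is aimed at plant-phenotyping and precision-horticulture
researchers who have (or want to prototype against) such a sensor rig.
It provides the full chain, each stage testable against simulated ground
truth:

* **Intrinsic calibration** of the thermal camera from an actively
  heated lightbulb board (5 × 6 bulbs, 100 mm spacing): staged
  multi-threshold blob detection with preset escalation, canonical grid
  ordering, and planar bundle adjustment minimising
  `sum_ij ||o_ij − ô(A, D, R_i, t_i, O_j)||²` over the camera matrix
  `A = [[fx, 0, cx], [0, fy, cy], [0, 0, 1]]`, the distortion
  coefficients `D = (k1, k2, k3, p1, p2)` and per-view board poses.
* **Extrinsic calibration** LiDAR → camera: box crop, RANSAC plane with
  a board-dimension check, PCA + minimum-rectangle pose initialisation,
  ICP refinement against a synthetic board model
  (`T_final = T_initial ∘ T_corr`), reprojection-minimising pose solve
  from the 30 bulb pairs, and cross-scan selection by
  `rmse = sqrt(Σ_i Σ_j ||m'_ij − m_ij||² / (N·M))`.
* **Fusion**: every point projects through the calibrated model and
  takes its nearest pixel's temperature; out-of-view points get the
  −10 °C sentinel and are never dropped.
* **Fruit segmentation**: per-point eigenvalue curvature
  `c = λ3/(λ1+λ2+λ3)` (scaled 0–100 per cloud) and backscattered
  reflectance, thresholded at density valleys (`C_th ≤ C`, `R_th ≤ R`),
  single-linkage clustering, per-fruit FST mean/min/max/SD, east/west
  side labels, stem localisation and cylindrical tree cuts.
* **Simulators** (moving line scanner + thermal renderer over analytic
  scenes: calibration board, 15-sphere metal evaluation tree, apple-tree
  row) and **metrics** (RMSE, MBE, adjusted R², detection F1).

File formats: PLY (ascii/binary) with `reflectance`/`temperature`
vertex properties, XYZ text, 32-bit float radiometric TIFF, CSV grids,
and JSON/YAML calibration files.

## Worked example

Simulate a calibration scan, detect the heated bulbs, and fuse the
thermal frame into the cloud:

```r
library(thermocloud)

sim  <- simulate_calibration_scene(seed = 1)
view <- staged_blob_detection(sim$image, pattern_spec())
view
#> Calibration view: ok (30 features, sensitivity 2, 2 attempts)

fused <- fuse_temperature(sim$cloud, sim$image,
                          sim$truth$camera, sim$truth$extrinsics)
fused
#> Point cloud: 165000 points [scanner]
#>   attributes: reflectance, temperature
#>   extent: x [1.477, 2.521]  y [0.000, 0.799]  z [0.000, 1.301] m
range(fused$temperature)
#> [1] -10.00000  46.48748
```

All 30 bulbs are found (the first sensitivity preset rejects the
rendered blob size, the second accepts it — the staged escalation doing
its job), and the fused cloud spans from the −10 °C out-of-view sentinel
to the ~46 °C bulb centres sitting on a ~21.4 °C board.

Recover the rig extrinsics end-to-end from ten simulated board scans
(5 mm range noise, 0.2 px blob noise):

```r
study <- extrinsic_recovery_study(n_scans = 10, seed = 1)
study$solution
#> Extrinsic solution: selected element-wise mean (RMSE 0.9180 px; mean candidate 0.9180 px)
c(rot_deg = study$rotation_error_deg, t_mm = 1000 * study$translation_error_m)
#>   rot_deg      t_mm
#> 0.2077759 4.2994255
```

The selected transform reproduces the generating extrinsics to a
fraction of a degree and a few millimetres, and its cross-scan
reprojection RMSE is of order one pixel.

Run the fruit pipeline on the standard synthetic orchard (5 trees,
10 fruits each, +0.5 °C east-side offset):

```r
orc <- orchard_recovery_study(seed = 42)
orc$detection
#> Detection: TP 45 FP 1 FN 5  P 0.978 R 0.900 F1 0.938
c(max_fst_err = orc$max_abs_fst_error, offset = orc$offset_estimate)
#> max_fst_err      offset
#>   0.1061127   0.5309893
```

45 of 50 fruits are recovered; every recovered fruit's FST mean is
within ~0.1 °C of its generating truth, and the simulated east−west
temperature offset is recovered.

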