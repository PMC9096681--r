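test_that("8-bit rescaling maps endpoints, midpoint and clips", {
  img <- thermal_image(matrix(c(20, 40, 60, 10, 70, 35), 2, 3))
  s <- scale_to_8bit(img, temperature_range(20, 60))
  expect_identical(s[1, 1], 0L)     # v = low
  expect_identical(s[1, 2], 255L)   # v = high
  expect_identical(s[2, 1], 128L)   # half-up rounding of 127.5
  expect_identical(s[1, 3], 255L)   # clipped above (70 degC)
  expect_identical(s[2, 2], 0L)     # clipped below (10 degC)
  # monotone in v
  v <- thermal_image(matrix(seq(15, 65, length.out = 100), 10, 10))
  sv <- scale_to_8bit(v, temperature_range(20, 60))
  expect_true(all(diff(as.vector(sv)) >= 0))
  expect_error(temperature_range(60, 60), "degenerate")
})

test_that("narrowing the temperature range suppresses the board and keeps
          the blob bright", {
  img <- thermal_image(rbind(c(46, 21), c(46, 21)))  # blob col, board col
  wide <- scale_to_8bit(img, temperature_range(20, 60))
  narrow <- scale_to_8bit(img, temperature_range(35, 60))
  # raising the lower bound clips the 21 degC board to black while the
  # 46 degC blob stays bright: the background is what loses level
  expect_gt(wide[1, 2], 0L)
  expect_identical(narrow[1, 2], 0L)
  expect_gt(narrow[1, 1], 100L)
  # relative blob/board contrast increases
  expect_gt(narrow[1, 1] / (narrow[1, 2] + 1),
            wide[1, 1] / (wide[1, 2] + 1))
})

test_that("blob detection recovers synthetic hot spots to sub-pixel", {
  truth <- cbind(x = c(50, 120, 200, 260, 150),
                 y = c(40, 60, 100, 150, 170))
  img8 <- spot_image8(300, 200, truth, sigma = 5)
  blobs <- detect_blobs(img8, sensitivity_preset(2, 20, 220, 15, 80, 350))
  expect_equal(nrow(blobs), 5)
  # centroid oracle: direct intensity-weighted centroiding per spot
  for (i in seq_len(5)) {
    d <- sqrt((blobs$x - truth[i, 1])^2 + (blobs$y - truth[i, 2])^2)
    expect_lt(min(d), 0.5)
  }
  # blank image and sub-minArea spots
  expect_equal(nrow(detect_blobs(matrix(0L, 100, 100),
                                 sensitivity_preset(1, 20, 220, 15,
                                                    160, 230))), 0)
  tiny <- spot_image8(100, 100, cbind(50, 50), sigma = 1.2)
  expect_equal(nrow(detect_blobs(tiny,
                                 sensitivity_preset(1, 20, 220, 15,
                                                    160, 230))), 0)
})

test_that("blob detection is equivariant to whole-pixel translation", {
  truth <- cbind(x = c(60, 150), y = c(60, 120))
  img8 <- spot_image8(220, 180, truth, sigma = 5)
  shifted <- spot_image8(220, 180, truth + 7, sigma = 5)
  p <- sensitivity_preset(2, 20, 220, 15, 80, 350)
  b0 <- detect_blobs(img8, p)
  b1 <- detect_blobs(shifted, p)
  expect_equal(b1$x, b0$x + 7, tolerance = 1e-6)
  expect_equal(b1$y, b0$y + 7, tolerance = 1e-6)
})

test_that("near-merged spots are separated by a finer preset", {
  truth <- cbind(x = c(100, 117), y = c(80, 80))
  img8 <- spot_image8(220, 160, truth, sigma = 5)
  coarse <- detect_blobs(img8, sensitivity_preset(1, 20, 60, 15, 160, 900))
  fine <- detect_blobs(img8, sensitivity_preset(2, 60, 220, 15, 20, 350))
  expect_lt(nrow(coarse), 2)  # low thresholds merge the pair
  expect_equal(nrow(fine), 2) # higher thresholds separate it
})

test_that("staged detection succeeds on a clean board and counts attempts", {
  sim <- simulate_calibration_scene(noise = list(range = 0, pixel = 0),
                                    seed = 3)
  v <- staged_blob_detection(sim$image, pattern_spec())
  expect_identical(v$status, "ok")
  expect_equal(nrow(v$features), 30)
  # features coincide with projected bulb truth
  px <- project_point(sim$truth$camera,
                      transform_points(sim$truth$extrinsics,
                                       sim$truth$bulbs))
  expect_lt(max(abs(v$features - px)), 0.5)
})

test_that("a view with an occluded bulb is discarded after 12 attempts", {
  sim <- simulate_calibration_scene(noise = list(range = 0, pixel = 0),
                                    seed = 4)
  vals <- sim$image$values
  # blank out one bulb: overwrite its hot spot with board temperature
  px <- project_point(sim$truth$camera,
                      transform_points(sim$truth$extrinsics,
                                       sim$truth$bulbs))
  cx <- round(px[1, 1]); cy <- round(px[1, 2])
  vals[(cy - 15):(cy + 15) + 1, (cx - 15):(cx + 15) + 1] <- 21.4
  v <- staged_blob_detection(thermal_image(vals), pattern_spec())
  expect_identical(v$status, "discarded")
  expect_equal(v$attempts, 12L)
})

test_that("staged detection tries at most n_ranges x 3 detector runs", {
  blank <- thermal_image(matrix(runif(64 * 48, 20, 21), 48, 64))
  v <- staged_blob_detection(blank, pattern_spec(), n_ranges = 4)
  expect_identical(v$status, "discarded")
  expect_lte(v$attempts, 12L)
})

test_that("grid sorting is canonical and rotation invariant", {
  ps <- pattern_spec()
  g3 <- pattern_grid(ps)
  # synthetic image coordinates: x right, y down (top row first)
  g <- cbind(g3[, 1] * 400 + 320, -g3[, 2] * 400 + 240)
  set.seed(20)
  perm <- sample(nrow(g))
  s0 <- sort_blobs_grid(g[perm, ], ps)
  expect_equal(unname(s0), unname(g), tolerance = 1e-9)
  for (ang in c(-30, -15, 15, 30) * pi / 180) {
    Rz <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    gr <- sweep(sweep(g, 2, c(320, 240)) %*% t(Rz), 2, c(320, 240), "+")
    sr <- sort_blobs_grid(gr[perm, ], ps)
    expect_equal(unname(sr), unname(gr), tolerance = 1e-9)
  }
  expect_error(sort_blobs_grid(g[1:29, ], ps), "29")
})

test_that("projection matches the pinhole closed form and hand-derived
          distortion values", {
  # optical axis
  c0 <- camera_intrinsics(500, 450, 321.5, 239.5)
  expect_equal(unname(project_point(c0, matrix(c(0, 0, 1), 1))[1, ]),
               c(321.5, 239.5))
  # pinhole example
  c1 <- camera_intrinsics(600, 600, 320, 240)
  expect_equal(unname(project_point(c1, matrix(c(0.1, 0.2, 1), 1))[1, ]),
               c(380, 360))
  # radial distortion on a normalized point: x_d = 0.5 (1 + 0.1 * 0.25)
  c2 <- camera_intrinsics(1, 1, 0, 0, k1 = 0.1)
  expect_equal(unname(project_point(c2, matrix(c(0.5, 0, 1), 1))[1, 1]),
               0.5125, tolerance = 1e-12)
  # D = 0 equals the closed form exactly on random points
  set.seed(21)
  pts <- cbind(runif(50, -0.5, 0.5), runif(50, -0.5, 0.5),
               runif(50, 0.5, 3))
  px <- project_point(c1, pts)
  expect_equal(px[, 1], 600 * pts[, 1] / pts[, 3] + 320)
  expect_equal(px[, 2], 600 * pts[, 2] / pts[, 3] + 240)
  expect_error(project_point(c1, matrix(c(0, 0, -1), 1)), "behind")
})

test_that("intrinsic calibration recovers the generating camera", {
  cam <- default_camera()
  sv <- simulate_calibration_views(cam, n_views = 12, pixel_noise = 0,
                                   seed = 7)
  fit <- calibrate_intrinsics(sv$views, pattern_spec())
  expect_lt(abs(fit$intrinsics$fx - cam$fx) / cam$fx, 0.005)
  expect_lt(abs(fit$intrinsics$fy - cam$fy) / cam$fy, 0.005)
  expect_lt(abs(fit$intrinsics$cx - cam$cx) / cam$cx, 0.005)
  expect_lt(abs(fit$intrinsics$cy - cam$cy) / cam$cy, 0.005)
  expect_lt(abs(fit$intrinsics$k1 - cam$k1), 0.1 * abs(cam$k1))
  # noiseless data drives the reprojection residual to numerical zero
  expect_lt(fit$rmse, 1e-3)
})

test_that("reprojection RMSE tracks the injected feature noise", {
  cam <- default_camera()
  sv <- simulate_calibration_views(cam, n_views = 12, pixel_noise = 0.2,
                                   seed = 8)
  fit <- calibrate_intrinsics(sv$views, pattern_spec())
  expect_gt(fit$rmse, 0.1)
  expect_lt(fit$rmse, 0.4) # within a factor 2 of the 0.2 px noise
})

test_that("degenerate view sets are refused", {
  cam <- default_camera()
  sv <- simulate_calibration_views(cam, n_views = 5, seed = 9)
  expect_error(calibrate_intrinsics(sv$views[1:2], pattern_spec()),
               "insufficient")
  expect_error(calibrate_intrinsics(rep(sv$views[1], 5), pattern_spec()),
               "degenerate")
})
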