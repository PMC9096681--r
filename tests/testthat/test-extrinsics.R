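test_that("crop_box matches an exhaustive membership oracle", {
  set.seed(40)
  cl <- point_cloud(matrix(runif(300, -2, 2), 100, 3),
                    reflectance = runif(100))
  bounds <- c(-1, 1, -0.5, 1.5, -2, 0.5)
  cr <- crop_box(cl, bounds)
  keep <- apply(cl$points, 1, function(p)
    p[1] > bounds[1] && p[1] < bounds[2] && p[2] > bounds[3] &&
      p[2] < bounds[4] && p[3] > bounds[5] && p[3] < bounds[6])
  expect_equal(n_points(cr), sum(keep))
  expect_equal(cr$reflectance, cl$reflectance[keep])
  # box containing everything is the identity
  all_in <- crop_box(cl, c(-3, 3, -3, 3, -3, 3))
  expect_equal(all_in$points, cl$points)
  # disjoint box is empty, with a warning rather than an error
  expect_warning(empty <- crop_box(cl, c(10, 11, 10, 11, 10, 11)),
                 "no points")
  expect_equal(n_points(empty), 0)
})

test_that("RANSAC plane location recovers a noisy board among outliers", {
  set.seed(41)
  ps <- pattern_spec()
  # board plane points (in-plane uniform) plus 20 % uniform box outliers
  n_in <- 4000
  u <- runif(n_in, -0.25, 0.25); v <- runif(n_in, -0.3, 0.3)
  T0 <- rigid_transform(thermocloud:::rot_y(0.3) %*%
                          thermocloud:::rot_x(0.1), c(1.5, 0.2, 0.4))
  plane_pts <- transform_points(T0, cbind(u, v, rnorm(n_in, 0, 0.003)))
  out_pts <- cbind(runif(1500, 0.5, 2.5), runif(1500, -1, 1),
                   runif(1500, -0.5, 1.2))
  # clutter stands clear of the board slab (walls/floor, not co-planar)
  nrm <- T0$R[, 3]
  slab <- abs(sweep(out_pts, 2, T0$t) %*% nrm) < 0.05
  out_pts <- out_pts[!slab, ][1:1000, ]
  cl <- point_cloud(rbind(plane_pts, out_pts))
  loc <- locate_pattern_plane(cl, ps, ransac_threshold = 0.01,
                              min_inliers = 1000)
  labels <- rep(c(TRUE, FALSE), c(n_in, 1000))
  recovered <- mean(which(labels) %in% loc$inliers)
  expect_gt(recovered, 0.99)
  # noiseless plane: normal within 1e-6 rad of truth
  cl0 <- point_cloud(transform_points(T0, cbind(u, v, 0)))
  loc0 <- locate_pattern_plane(cl0, ps, min_inliers = 1000)
  nrm <- T0$R[, 3]
  ang <- acos(min(1, abs(sum(loc0$normal * nrm))))
  expect_lt(ang, 1e-6)
})

test_that("a cut-off board fails the dimension check", {
  set.seed(42)
  ps <- pattern_spec()
  u <- runif(4000, -0.25, 0.25); v <- runif(4000, -0.3, 0)  # half board
  cl <- point_cloud(cbind(u + 1.5, v, rnorm(4000, 0, 0.002)))
  expect_error(locate_pattern_plane(cl, ps, min_inliers = 500),
               "dimension mismatch")
})

test_that("PCA pose recovers canonical and rotated board placements", {
  set.seed(43)
  ps <- pattern_spec()
  u <- runif(6000, -0.25, 0.25); v <- runif(6000, -0.3, 0.3)
  # canonical: board facing -x from a sensor at the origin
  R0 <- thermocloud:::rot_z(-pi / 2) %*% thermocloud:::rot_x(pi / 2)
  T0 <- rigid_transform(R0, c(2, 0.1, 0.35))
  cl <- point_cloud(transform_points(T0, cbind(u, v, 0)))
  Ti <- initial_pose_pca(cl)
  expect_lt(max(abs(Ti$t - T0$t)), 0.005)
  expect_lt(rotation_angle_deg(Ti, T0), 0.5)
  # known extra rotation
  T1 <- rigid_transform(R0 %*% thermocloud:::rot_z(0.15) %*%
                          thermocloud:::rot_y(0.2), c(1.6, 0, 0.5))
  cl1 <- point_cloud(transform_points(T1, cbind(u, v, rnorm(6000, 0, 0.002))))
  Ti1 <- initial_pose_pca(cl1)
  expect_lt(rotation_angle_deg(Ti1, T1), 2)
  expect_error(initial_pose_pca(point_cloud(cbind(1:10, 0, 0) * 0.01)),
               "collinear")
})

test_that("eigen decomposition behind the pose matches a dense oracle", {
  set.seed(44)
  u <- runif(800, -0.25, 0.25); v <- runif(800, -0.3, 0.3)
  cl <- point_cloud(cbind(u, v, rnorm(800, 0, 0.002)) + 1)
  ds <- planar_downsample(cl, 0.02)
  p <- ds$points
  ev <- eigen(crossprod(sweep(p, 2, colMeans(p))) / nrow(p),
              symmetric = TRUE)
  # brute-force covariance eigen oracle
  C <- cov(p) * (nrow(p) - 1) / nrow(p)
  ev2 <- eigen(C, symmetric = TRUE)
  expect_equal(ev$values, ev2$values, tolerance = 1e-9)
})

test_that("board model sampling has the closed-form grid count", {
  ps <- pattern_spec()
  m <- sample_pattern_model(ps, 0.005)
  expect_equal(n_points(m), 101 * 121)
  expect_true(all(m$points[, 3] == 0))
  expect_equal(diff(range(m$points[, 1])), ps$board_width)
  expect_equal(diff(range(m$points[, 2])), ps$board_height)
})

test_that("ICP recovers a displaced board pose and is monotone", {
  set.seed(45)
  ps <- pattern_spec()
  model <- sample_pattern_model(ps, 0.01)
  T_true <- rigid_transform(thermocloud:::rot_z(0.05) %*%
                              thermocloud:::rot_y(0.04),
                            c(1.5, 0.3, 0.2))
  # data is the displaced model itself; an initial guess within the
  # capture range (inside half the grid pitch) must snap back exactly
  data <- cloud_transform(model, T_true)
  T_init <- t_compose(T_true, rigid_transform(thermocloud:::rot_z(0.01),
                                              c(0.004, -0.003, 0.003)))
  icp <- refine_pose_icp(model, data, T_init)
  expect_lt(rotation_angle_deg(icp$T_final, T_true), 0.1)
  expect_lt(sqrt(sum((icp$T_final$t - T_true$t)^2)), 0.001)
  # RMS correspondence distance never increases
  expect_true(all(diff(icp$history) <= 1e-10))
  # an irregular (non-lattice) board sample registers to the few-mm
  # level limited by the model grid resolution
  data2 <- cloud_transform(point_cloud(cbind(runif(6000, -0.25, 0.25),
                                             runif(6000, -0.3, 0.3), 0)),
                           T_true)
  T_init2 <- rigid_transform(thermocloud:::rot_z(0.02),
                             c(1.52, 0.27, 0.22))
  icp2 <- refine_pose_icp(model, data2, T_init2)
  expect_lt(rotation_angle_deg(icp2$T_final, T_true), 0.3)
  expect_lt(sqrt(sum((icp2$T_final$t - T_true$t)^2)), 0.012)
  expect_true(all(diff(icp2$history) <= 1e-10))
  # identical clouds, identity start: correction stays identity
  icp0 <- refine_pose_icp(model, model, rigid_transform())
  expect_lt(rotation_angle_deg(icp0$T_corr), 1e-6)
  expect_lt(max(abs(icp0$T_corr$t)), 1e-9)
})

test_that("the final pose composes as initial then correction", {
  set.seed(46)
  ps <- pattern_spec()
  model <- sample_pattern_model(ps, 0.01)
  T_true <- rigid_transform(thermocloud:::rot_y(0.06), c(1.4, 0.2, 0.3))
  data <- cloud_transform(model, T_true)
  T_init <- rigid_transform(diag(3), c(1.42, 0.18, 0.31))
  icp <- refine_pose_icp(model, data, T_init)
  via_parts <- transform_points(
    icp$T_corr, model$points) # board-frame correction first
  via_parts <- transform_points(T_init, via_parts)
  via_final <- transform_points(icp$T_final, model$points)
  expect_equal(via_parts, via_final, tolerance = 1e-9)
})

test_that("bulb positions follow rigid maps and preserve spacing", {
  ps <- pattern_spec()
  expect_equal(bulb_positions(rigid_transform(), ps), pattern_grid(ps))
  shifted <- bulb_positions(rigid_transform(diag(3), c(1, 0, 0)), ps)
  expect_equal(shifted, pattern_grid(ps) + rep(c(1, 0, 0), each = 30))
  set.seed(47)
  L <- bulb_positions(random_transform(), ps)
  # adjacent (same-row) bulbs stay 0.100 m apart
  for (r in 0:4) {
    row <- L[r * 6 + 1:6, ]
    expect_equal(sqrt(rowSums(diff(row)^2)), rep(0.1, 5),
                 tolerance = 1e-12)
  }
})

test_that("extrinsic solving recovers generative poses", {
  set.seed(48)
  cam <- default_camera()
  ps <- pattern_spec()
  T_true <- t_compose(
    rigid_transform(rbind(c(0, -1, 0), c(0, 0, -1), c(1, 0, 0)),
                    c(0.02, 0.21, -0.01)),
    rigid_transform(diag(3), c(0, -0.4, 0)))
  # planar (board) configuration
  board <- board_pose_sample()
  L <- transform_points(board, pattern_grid(ps))
  px <- project_point(cam, transform_points(T_true, L))
  sol <- solve_extrinsics(px, L, cam)
  expect_lt(rotation_angle_deg(sol, T_true), 0.05)
  expect_lt(sqrt(sum((sol$t - T_true$t)^2)), 0.001)
  # general 3D configuration
  L2 <- cbind(runif(30, 1, 2), runif(30, -0.5, 1), runif(30, -0.3, 0.8))
  px2 <- project_point(cam, transform_points(T_true, L2))
  sol2 <- solve_extrinsics(px2, L2, cam)
  expect_lt(rotation_angle_deg(sol2, T_true), 0.05)
  expect_lt(sqrt(sum((sol2$t - T_true$t)^2)), 0.001)
  # guards
  expect_error(solve_extrinsics(px2[1:3, ], L2[1:3, ], cam),
               "insufficient")
  Lc <- cbind(seq(1, 2, length.out = 10), 0.2, 0.3) # collinear
  expect_error(solve_extrinsics(px2[1:10, ], Lc, cam), "degenerate")
})

test_that("translation error stays below 10 mm under pixel noise", {
  set.seed(49)
  cam <- default_camera()
  T_true <- rigid_transform(rbind(c(0, -1, 0), c(0, 0, -1), c(1, 0, 0)),
                            c(0, 0.2, 0))
  errs <- replicate(25, {
    L <- cbind(runif(30, 0.8, 1.2), runif(30, -0.4, 0.4),
               runif(30, -0.3, 0.3))
    px <- project_point(cam, transform_points(T_true, L)) +
      matrix(rnorm(60, 0, 0.5), ncol = 2)
    sol <- solve_extrinsics(px, L, cam)
    sqrt(sum((sol$t - T_true$t)^2))
  })
  expect_lt(median(errs), 0.010)
})

test_that("cross-scan RMSE matches an explicit summation oracle", {
  set.seed(50)
  cam <- default_camera()
  T1 <- rigid_transform(rbind(c(0, -1, 0), c(0, 0, -1), c(1, 0, 0)),
                        c(0, 0.2, 0))
  scans <- lapply(1:2, function(i) {
    L <- cbind(runif(4, 0.8, 1.2), runif(4, -0.3, 0.3),
               runif(4, -0.2, 0.2))
    list(points = L,
         pixels = project_point(cam, transform_points(T1, L)) +
           matrix(rnorm(8, 0, 1), ncol = 2))
  })
  sol <- cross_scan_rmse(list(T1), scans, cam)
  # explicit Eq-style summation: sqrt(sum ||m' - m||^2 / (N M))
  ss <- 0
  for (sc in scans) {
    proj <- project_point(cam, transform_points(T1, sc$points))
    ss <- ss + sum((proj - sc$pixels)^2)
  }
  expect_equal(sol$per_candidate_rmse[1], sqrt(ss / 8), tolerance = 1e-12)
  # single perfect candidate on noiseless scans has RMSE 0 and is selected
  clean <- lapply(scans, function(sc) {
    sc$pixels <- project_point(cam, transform_points(T1, sc$points)); sc
  })
  sol0 <- cross_scan_rmse(list(T1), clean, cam)
  expect_lt(sol0$rmse, 1e-12)
  expect_true(identical(sol0$selected, 1L) ||
                identical(sol0$selected, "mean"))
  # the selected solution never has higher RMSE than the mean candidate
  set.seed(51)
  cands <- lapply(1:3, function(i)
    rigid_transform(T1$R %*% thermocloud:::rot_z(rnorm(1, 0, 0.002)),
                    T1$t + rnorm(3, 0, 0.002)))
  sol3 <- cross_scan_rmse(cands, scans, cam)
  expect_lte(sol3$rmse, sol3$mean_candidate_rmse)
  expect_lte(sol3$rmse, min(sol3$per_candidate_rmse))
})
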