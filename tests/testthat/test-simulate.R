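test_that("ray caster agrees with closed-form intersections", {
  scene <- thermocloud:::empty_scene()
  scene <- thermocloud:::scene_add_sphere(scene, c(2, 0, 0), 0.5,
                                          class = "sphere", temp_base = 20,
                                          refl_mean = 50)
  scene <- thermocloud:::scene_add_rect(scene, c(5, 0, 0), c(0, 1, 0),
                                        c(0, 0, 1), 2, 2, class = "wall",
                                        temp_base = 15, refl_mean = 30)
  # axial ray hits the sphere at t = 1.5
  h <- scene_raycast(scene, matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1))
  expect_equal(h$t[1], 1.5, tolerance = 1e-9)
  expect_equal(h$id[1], 1L)
  # oblique ray misses the sphere, hits the wall plane at x = 5
  d <- c(1, 0.3, 0.1); d <- d / sqrt(sum(d^2))
  h2 <- scene_raycast(scene, matrix(0, 1, 3), matrix(d, 1))
  expect_equal(h2$id[1], 2L)
  expect_equal(h2$t[1] * d[1], 5, tolerance = 1e-9)
  # closed-form quadratic for a random set of sphere rays
  set.seed(60)
  for (i in 1:50) {
    o <- runif(3, -1, 1)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    h3 <- scene_raycast(scene, matrix(o, 1), matrix(dir, 1))
    e <- o - c(2, 0, 0)
    B <- 2 * sum(e * dir); C <- sum(e^2) - 0.25
    disc <- B^2 - 4 * C
    roots <- if (disc < 0) numeric(0) else
      (-B + c(-1, 1) * sqrt(disc)) / 2
    roots <- roots[roots > 1e-9]
    if (length(roots) && min(roots) < (5 - o[1]) / max(dir[1], 1e-9))
      expect_equal(h3$t[1], min(roots), tolerance = 1e-9)
  }
})

test_that("cylinder and disk intersections match analytic solutions", {
  scene <- thermocloud:::empty_scene()
  scene <- thermocloud:::scene_add_cylinder(scene, c(3, 0, -1), c(0, 0, 1),
                                            2, 0.2, class = "trunk",
                                            temp_base = 18, refl_mean = 50)
  scene <- thermocloud:::scene_add_disk(scene, c(1, 0, 0.5), c(1, 0, 0),
                                        0.3, class = "leaf",
                                        temp_base = 17, refl_mean = 45)
  # horizontal ray into the cylinder: t = 3 - 0.2
  h <- scene_raycast(scene, matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1))
  expect_equal(h$t[1], 2.8, tolerance = 1e-12)
  # ray above the cylinder cap misses it
  h2 <- scene_raycast(scene, matrix(c(0, 0, 1.5), 1),
                      matrix(c(1, 0, 0), 1))
  expect_true(is.na(h2$t[1]))
  # disk hit inside the radius, miss outside
  h3 <- scene_raycast(scene, matrix(c(0, 0.2, 0.5), 1),
                      matrix(c(1, 0, 0), 1))
  expect_equal(h3$id[1], 2L)
  # past the disk rim at y = 0.5 (> both radii): no hit at all
  h4 <- scene_raycast(scene, matrix(c(0, 0.5, 0.5), 1),
                      matrix(c(1, 0, 0), 1))
  expect_true(is.na(h4$t[1]))
})

test_that("scan profiles and the assembled cloud agree", {
  scene <- thermocloud:::empty_scene()
  scene <- thermocloud:::scene_add_rect(scene, c(1.5, 0.2, 0.3),
                                        c(0, 1, 0), c(0, 0, 1), 0.3, 0.3,
                                        class = "wall", temp_base = 20,
                                        refl_mean = 50)
  set.seed(61)
  scan <- simulate_lidar_scan(scene, travel = 0.4, range_noise = 0.002)
  via_profiles <- assemble_profiles(scan$profiles, speed = 0.020,
                                    scan_rate = 25)
  expect_equal(unname(via_profiles$points), unname(scan$cloud$points),
               tolerance = 1e-12)
  expect_equal(via_profiles$reflectance, scan$cloud$reflectance)
})

test_that("simulators are deterministic for a fixed seed", {
  a <- simulate_calibration_scene(seed = 11)
  b <- simulate_calibration_scene(seed = 11)
  expect_identical(a$cloud$points, b$cloud$points)
  expect_identical(a$image$values, b$image$values)
  c <- simulate_calibration_scene(seed = 12)
  expect_false(identical(a$cloud$points, c$cloud$points))
})

test_that("board scan points satisfy the plane equation to the noise
          level", {
  sim <- simulate_calibration_scene(noise = list(range = 0.005,
                                                 pixel = 0),
                                    seed = 13)
  board <- sim$cloud$points[sim$ids == 1, ]
  tb <- sim$truth$board_pose
  res <- sweep(board, 2, tb$t) %*% tb$R[, 3]
  # residual scatter is of the order of the range noise (incidence
  # shortens the normal component, so allow a band around 5 mm)
  expect_gt(sd(res), 0.002)
  expect_lt(sd(res), 0.008)
  # noiseless points lie exactly on the plane
  sim0 <- simulate_calibration_scene(noise = list(range = 0, pixel = 0),
                                     seed = 13)
  board0 <- sim0$cloud$points[sim0$ids == 1, ]
  res0 <- sweep(board0, 2, tb$t) %*% tb$R[, 3]
  expect_lt(max(abs(res0)), 1e-9)
})

test_that("rendered pixels carry the first-hit surface temperature", {
  sim <- simulate_metal_frame(noise = list(range = 0, pixel = 0),
                              temps = c(S_W = 21, S_B = 23), seed = 14)
  img <- sim$image
  scene <- sim$truth$scene
  cam <- sim$truth$camera
  # re-derive a handful of pixel rays and compare against the truth
  set.seed(15)
  T_cw <- t_inverse(sim$truth$extrinsics)
  for (i in 1:50) {
    px <- c(sample(0:639, 1), sample(0:479, 1))
    nxy <- thermocloud:::undistort_pixels(cam, matrix(px, 1))
    dir <- as.numeric(T_cw$R %*% c(nxy[1], nxy[2], 1))
    hit <- scene_raycast(scene, matrix(T_cw$t, 1), matrix(dir, 1))
    want <- if (is.na(hit$id[1])) 19
      else thermocloud:::scene_temperature_at(scene, hit$id[1],
                                              hit$points)
    expect_equal(img$values[px[2] + 1, px[1] + 1], want,
                 tolerance = 1e-9)
  }
})

test_that("metal frame carries 15 spheres and rejects overlaps", {
  lay <- default_sphere_layout()
  expect_equal(nrow(lay), 15)
  expect_equal(sum(lay$radius == 0.060), 3)
  bad <- lay
  bad$y[2] <- bad$y[1]; bad$z[2] <- bad$z[1]; bad$x[2] <- bad$x[1]
  expect_error(simulate_metal_frame(spheres = bad, seed = 1),
               "overlap")
})

test_that("orchard truth has the configured structure", {
  orc <- simulate_orchard_row(n_trees = 3, fruits_per_tree = 6, seed = 16,
                              leaf_density = 20)
  tt <- orc$truth$fruits
  expect_equal(nrow(tt), 18)
  expect_equal(as.vector(table(tt$tree)), rep(6L, 3))
  # stems spaced at the tree pitch
  expect_equal(diff(orc$truth$stems[, 2]), rep(0.95, 2))
  # east offset enters the truth temperatures
  expect_gt(mean(tt$temp[tt$side == "east"]),
            mean(tt$temp[tt$side == "west"]))
  # every point is traceable to a surface id
  expect_true(all(orc$sides$east$ids %in% orc$truth$scene$surfaces$id))
})
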