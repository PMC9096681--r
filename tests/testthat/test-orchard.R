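# Small geometric fixtures exercise each stage; the full synthetic
# orchard is covered by the end-to-end acceptance suite.

test_that("side alignment recovers a known displacement and keeps
          provenance", {
  set.seed(70)
  pts <- rbind(sphere_points(400, c(0, 0, 1), 0.3),
               cbind(runif(400, -0.5, 0.5), runif(400, -0.5, 0.5),
                     runif(400, 0, 2)))
  a <- point_cloud(pts)
  T_true <- rigid_transform(thermocloud:::rot_z(0.03), c(0.02, -0.01, 0.015))
  b <- cloud_transform(a, t_inverse(T_true))
  # init near the truth
  init <- rigid_transform(thermocloud:::rot_z(0.025), c(0.015, -0.012, 0.01))
  al <- align_tree_sides(a, b, init = init, voxel = 0.02)
  expect_lt(rotation_angle_deg(al$transform, T_true), 0.3)
  expect_lt(sqrt(sum((al$transform$t - T_true$t)^2)), 0.005)
  expect_lt(al$mean_dist, 0.015)
  expect_equal(n_points(al$cloud), 2 * n_points(a))
  expect_equal(sum(al$cloud$extra$side == 0), n_points(a))
  # identical clouds with identity init refine to identity
  al0 <- align_tree_sides(a, a, voxel = 0.02)
  expect_lt(rotation_angle_deg(al0$transform), 0.05)
  expect_lt(max(abs(al0$transform$t)), 1e-3)
})

test_that("stem detection finds a row of trunks within half a bin", {
  set.seed(71)
  pitch <- 0.95
  stems_y <- (0:4) * pitch + 0.5
  pts <- do.call(rbind, lapply(stems_y, function(y) {
    ang <- runif(600, 0, 2 * pi)
    cbind(0.04 * cos(ang) + rnorm(600, 0, 0.003),
          y + 0.04 * sin(ang) + rnorm(600, 0, 0.003),
          runif(600, 0, 1.5))
  }))
  cl <- point_cloud(pts)
  stems <- detect_stems(cl, bin = 0.05, expected = 5)
  expect_equal(nrow(stems), 5)
  expect_lt(max(abs(stems[, 2] - stems_y)), 0.025)
  expect_lt(max(abs(stems[, 1])), 0.025)
  # single trunk
  one <- detect_stems(cloud_subset(cl, pts[, 2] < 1), expected = 1)
  expect_equal(nrow(one), 1)
})

test_that("histogram peaks equal a brute-force local-maxima scan", {
  set.seed(72)
  pts <- cbind(runif(3000, 0, 2), runif(3000, 0, 2), 0.5)
  cl <- point_cloud(pts)
  bin <- 0.1
  # brute-force oracle over the same histogram
  x0 <- min(pts[, 1]) - bin; y0 <- min(pts[, 2]) - bin
  ix <- floor((pts[, 1] - x0) / bin) + 1L
  iy <- floor((pts[, 2] - y0) / bin) + 1L
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  counts <- matrix(0L, nx, ny)
  counts[] <- as.integer(table(factor(ix, levels = 1:nx),
                               factor(iy, levels = 1:ny)))
  floor_count <- quantile(counts[counts > 0], 0.75)
  n_peaks <- 0
  for (i in 2:(nx - 1)) for (j in 2:(ny - 1)) {
    nb <- counts[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (counts[i, j] >= floor_count && counts[i, j] == max(nb) &&
        sum(nb == counts[i, j]) == 1)
      n_peaks <- n_peaks + 1
  }
  got <- detect_stems(cl, bin = bin, trunk_band = c(0, 1),
                      min_separation = 0)
  expect_gte(nrow(got), n_peaks) # plateaus counted once, never dropped
})

test_that("cylindrical tree segmentation equals the brute-force
          membership test", {
  set.seed(73)
  pts <- cbind(runif(2000, -1, 2), runif(2000, -1, 2), runif(2000, 0, 2))
  cl <- point_cloud(pts, reflectance = runif(2000))
  seg <- segment_tree(cl, c(0.3, 0.4), radius = 0.45)
  want <- which(sqrt((pts[, 1] - 0.3)^2 + (pts[, 2] - 0.4)^2) <= 0.45)
  expect_equal(seg$indices, want)
  # radius covering everything returns the whole cloud
  all_seg <- segment_tree(cl, c(0.5, 0.5), radius = 10)
  expect_equal(n_points(all_seg$cloud), 2000)
  # two stems 0.95 m apart with 0.45 m cylinders share no points
  s1 <- segment_tree(cl, c(0, 0), 0.45)
  s2 <- segment_tree(cl, c(0, 0.95), 0.45)
  expect_length(intersect(s1$indices, s2$indices), 0)
})

test_that("curvature is zero on planes and higher on spheres", {
  set.seed(74)
  plane <- point_cloud(cbind(runif(800, 0, 0.3), runif(800, 0, 0.3), 0))
  f_pl <- curvature_features(plane, k = 30)
  expect_true(all(f_pl$raw_curvature < 1e-12))
  # sphere of radius 0.04 m under identical sampling density
  sp <- point_cloud(sphere_points(800, r = 0.04))
  f_sp <- curvature_features(sp, k = 30)
  expect_gt(median(f_sp$raw_curvature), max(f_pl$raw_curvature))
  # eigenvalue ordering and positivity
  expect_true(all(diff(t(f_sp$eigenvalues)) <= 1e-15))
  expect_true(all(f_sp$eigenvalues >= 0))
})

test_that("per-neighbourhood eigenvalues match a dense eigen oracle", {
  set.seed(75)
  cl <- point_cloud(matrix(rnorm(3 * 300, sd = 0.1), 300, 3))
  k <- 12
  f <- curvature_features(cl, k = k)
  nn <- thermocloud:::knn_points(cl$points, cl$points, k)
  idx_check <- sample(300, 100)
  for (i in idx_check) {
    nbh <- cl$points[nn$idx[i, ], , drop = FALSE]
    C <- crossprod(sweep(nbh, 2, colMeans(nbh))) / k
    lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(unname(f$eigenvalues[i, ]), lam, tolerance = 1e-9)
  }
})

test_that("scaled curvature attains 0 and 100 on non-constant clouds", {
  set.seed(76)
  for (trial in 1:5) {
    pts <- rbind(cbind(runif(200, 0, 0.2), runif(200, 0, 0.2), 0),
                 sphere_points(200, c(0.5, 0.5, 0), 0.03))
    f <- curvature_features(point_cloud(pts), k = 15)
    expect_equal(min(f$curvature), 0)
    expect_equal(max(f$curvature), 100)
  }
})

test_that("duplicate-point neighbourhoods get curvature 0 with a flag", {
  pts <- rbind(matrix(0.5, 20, 3), matrix(rnorm(60), 20, 3))
  f <- curvature_features(point_cloud(pts), k = 10)
  expect_true(all(f$degenerate[1:20]))
  expect_true(all(f$raw_curvature[1:20] == 0))
})

test_that("threshold estimation finds the valley between separated
          modes", {
  set.seed(77)
  field <- structure(list(
    curvature = c(rnorm(500, 20, 5), rnorm(500, 80, 5)),
    reflectance = c(rnorm(500, 20, 5), rnorm(500, 80, 5))),
    class = "feature_field")
  th <- estimate_thresholds(field)
  expect_gt(th$C_th, 40); expect_lt(th$C_th, 60)
  expect_gt(th$R_th, 40); expect_lt(th$R_th, 60)
  expect_equal(unname(th$method["curvature"]), "kde_valley")
  # unimodal input falls back to the requested percentile
  uni <- structure(list(curvature = rnorm(1000, 50, 5),
                        reflectance = rnorm(1000, 50, 5)),
                   class = "feature_field")
  th2 <- estimate_thresholds(uni, params = list(p = 90))
  expect_equal(th2$R_th, unname(quantile(uni$reflectance, 0.9)),
               tolerance = 1e-9)
  # percentile method matches the direct quantile
  th3 <- estimate_thresholds(uni, method = "percentile",
                             params = list(p = 75))
  expect_equal(th3$C_th, unname(quantile(uni$curvature, 0.75)))
  # constant features are refused by name
  const <- structure(list(curvature = rnorm(100),
                          reflectance = rep(5, 100)),
                     class = "feature_field")
  expect_error(estimate_thresholds(const), "reflectance")
})

test_that("fruit clustering separates spheres and reports FST", {
  set.seed(78)
  # two fruits plus a leaf plane; reflectance separates them
  f1 <- sphere_points(300, c(0, 0, 1), 0.035)
  f2 <- sphere_points(300, c(0.2, 0, 1.3), 0.035)
  leaf <- cbind(runif(400, -0.3, 0.3), runif(400, -0.3, 0.3),
                runif(400, 0.5, 1.6))
  pts <- rbind(f1, f2, leaf)
  cl <- point_cloud(pts,
                    reflectance = c(rnorm(600, 75, 2), rnorm(400, 45, 2)),
                    temperature = c(rep(18.5, 300), rep(19.1, 300),
                                    rep(17.5, 400)))
  field <- curvature_features(cl, k = 20)
  th <- list(C_th = 0, R_th = 60)
  fruits <- segment_fruits(cl, field, th, cluster_eps = 0.02,
                           min_points = 30)
  expect_length(fruits, 2)
  ft <- fruit_table(fruits)
  ft <- ft[order(ft$x), ]
  expect_lt(max(abs(ft$x - c(0, 0.2))), 0.01)
  expect_equal(ft$fst_mean, c(18.5, 19.1))
  expect_equal(ft$fst_sd, c(0, 0))
  expect_lt(max(abs(ft$radius - 0.035)), 0.01)
  # thresholds above all features give an empty result
  expect_length(segment_fruits(cl, field, list(C_th = 1000, R_th = 1000)),
                0)
  # sentinel temperatures are excluded from the statistics
  cl2 <- cl
  cl2$temperature[1:50] <- -10
  fr2 <- segment_fruits(cl2, field, th)
  ft2 <- fruit_table(fr2)
  expect_equal(ft2$fst_mean[order(ft2$x)][1], 18.5)
})

test_that("east/west labelling follows the centroid offset and
          partitions", {
  mk <- function(x) structure(list(indices = 1:40, centroid = c(x, 0, 1),
                                   radius = 0.03,
                                   fst = list(mean = 18, min = 17,
                                              max = 19, sd = 0.2,
                                              n = 40),
                                   height = 1, side = NA_character_),
                              class = "fruit_segment")
  fruits <- list(mk(0.2), mk(-0.15), mk(0.3))
  lab <- categorize_side(fruits)
  expect_equal(vapply(lab, `[[`, "", "side"), c("east", "west", "east"))
  # mirrored set swaps labels exactly
  mirrored <- categorize_side(list(mk(-0.2), mk(0.15), mk(-0.3)))
  expect_equal(vapply(mirrored, `[[`, "", "side"),
               c("west", "east", "west"))
  # exact tie goes to east deterministically
  expect_message(tie <- categorize_side(list(mk(0))), "tie")
  expect_equal(tie[[1]]$side, "east")
})

test_that("fruit segmentation is invariant under rigid scene motion", {
  set.seed(79)
  f1 <- sphere_points(250, c(0, 0, 1), 0.035)
  leaf <- cbind(runif(300, -0.3, 0.3), runif(300, -0.3, 0.3),
                runif(300, 0.5, 1.5))
  cl <- point_cloud(rbind(f1, leaf),
                    reflectance = c(rnorm(250, 75, 2), rnorm(300, 45, 2)))
  th <- list(C_th = 0, R_th = 60)
  base <- segment_fruits(cl, curvature_features(cl, 20), th)
  Tm <- rigid_transform(thermocloud:::rot_z(0.4) %*%
                          thermocloud:::rot_x(0.2), c(1, -2, 0.5))
  moved <- cloud_transform(cl, Tm)
  rot <- segment_fruits(moved, curvature_features(moved, 20), th)
  expect_length(rot, length(base))
  expect_equal(transform_points(Tm, matrix(base[[1]]$centroid, 1)),
               matrix(rot[[1]]$centroid, 1), tolerance = 1e-6)
  expect_equal(sort(base[[1]]$indices), sort(rot[[1]]$indices))
})
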