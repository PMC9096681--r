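# Ground-truth scene simulators: a moving 2D line scanner and a thermal
# camera observing analytic surfaces (board, spheres, cylinders, leaf
# disks). Every emitted point and pixel is traceable to a surface id, so
# pipeline stages can be tested against generating truth without
# hardware. Same seed, same output: the generators are deterministic.

deg2rad <- function(d) d * pi / 180

# --- scene container -------------------------------------------------------
# surfaces: data.frame(id, class, temp_base, temp_vert, z_ref, refl_mean,
#                      material, fruit_id)
# geometry: spheres / rects / cyls / disks matrices in the encoding of
#           raycast_cpp (last column = id)
empty_scene <- function() {
  list(spheres = matrix(0, 0, 5), rects = matrix(0, 0, 12),
       cyls = matrix(0, 0, 9), disks = matrix(0, 0, 8),
       surfaces = data.frame(id = integer(0), class = character(0),
                             temp_base = numeric(0), temp_vert = numeric(0),
                             z_ref = numeric(0), refl_mean = numeric(0),
                             material = character(0),
                             fruit_id = integer(0)))
}

scene_add_surface <- function(scene, class, temp_base, refl_mean,
                              temp_vert = 0, z_ref = 0, material = "",
                              fruit_id = NA_integer_) {
  id <- nrow(scene$surfaces) + 1L
  scene$surfaces <- rbind(scene$surfaces, data.frame(
    id = id, class = class, temp_base = temp_base, temp_vert = temp_vert,
    z_ref = z_ref, refl_mean = refl_mean, material = material,
    fruit_id = fruit_id))
  scene
}

scene_add_sphere <- function(scene, centre, r, ...) {
  scene <- scene_add_surface(scene, z_ref = centre[3], ...)
  id <- nrow(scene$surfaces)
  scene$spheres <- rbind(scene$spheres, c(centre, r, id))
  scene
}

scene_add_rect <- function(scene, centre, u, v, hu, hv, ...) {
  scene <- scene_add_surface(scene, z_ref = centre[3], ...)
  id <- nrow(scene$surfaces)
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  scene$rects <- rbind(scene$rects, c(centre, u, v, hu, hv, id))
  scene
}

scene_add_cylinder <- function(scene, base, axis, len, r, ...) {
  scene <- scene_add_surface(scene, z_ref = base[3] + axis[3] * len / 2,
                             ...)
  id <- nrow(scene$surfaces)
  axis <- axis / sqrt(sum(axis^2))
  scene$cyls <- rbind(scene$cyls, c(base, axis, len, r, id))
  scene
}

scene_add_disk <- function(scene, centre, normal, r, ...) {
  scene <- scene_add_surface(scene, z_ref = centre[3], ...)
  id <- nrow(scene$surfaces)
  normal <- normal / sqrt(sum(normal^2))
  scene$disks <- rbind(scene$disks, c(centre, normal, r, id))
  scene
}

#' Cast rays against a simulated scene
#'
#' Nearest-positive-hit ray casting against the scene's analytic surfaces
#' (spheres, rectangles, finite cylinders, disks).
#'
#' @param scene a scene as built by the `simulate_*` generators.
#' @param origins,dirs N x 3 matrices of ray origins and directions.
#' @return List with `t` (hit parameter, NA when no hit), `id` (surface
#'   id) and `points` (N x 3 hit coordinates, NA rows when no hit).
#' @export
scene_raycast <- function(scene, origins, dirs) {
  origins <- as_points_matrix(origins)
  dirs <- as_points_matrix(dirs)
  hit <- raycast_cpp(origins, dirs, scene$spheres, scene$rects,
                     scene$cyls, scene$disks)
  pts <- origins + dirs * hit$t
  list(t = hit$t, id = hit$id, points = pts)
}

# temperature of scene surfaces at hit points (smooth vertical field)
scene_temperature_at <- function(scene, id, points) {
  s <- scene$surfaces[id, ]
  s$temp_base + s$temp_vert * (points[, 3] - s$z_ref)
}

# --- line-scanner sampling -------------------------------------------------

#' Simulate a moving 2D line-scanner pass over a scene
#'
#' The scanner sits at `origin_xz` in the scan plane (x horizontal, z up)
#' and travels along y at constant speed. Each profile sweeps a 180
#' degree fan (`dir = (s cos a, 0, sin a)`, `s = +1` scanning toward +x,
#' `-1` toward -x) on a uniform angular grid. Gaussian range noise is
#' added per return; per-point reflectance is the surface mean plus
#' Gaussian noise.
#'
#' @param scene scene to scan.
#' @param travel travel length, metres.
#' @param origin_xz scanner position in the scan plane, c(x, z), metres.
#' @param facing +1 to fan toward +x, -1 toward -x.
#' @param speed platform speed, m/s.
#' @param scan_rate profile rate, Hz.
#' @param angular_res angular resolution, degrees.
#' @param range_noise range noise SD, metres.
#' @param refl_noise reflectance noise SD, sensor units.
#' @param y_start travel-axis coordinate of the first profile.
#' @return List with `cloud` (assembled [point_cloud()] with reflectance),
#'   `ids` (per-point surface ids), `profiles` (list of [scan_profile()]).
#' @export
simulate_lidar_scan <- function(scene, travel, origin_xz = c(0, 0),
                                facing = 1, speed = 0.020, scan_rate = 25,
                                angular_res = 0.1667, range_noise = 0.005,
                                refl_noise = 2, y_start = 0) {
  angles <- seq(0, pi, by = deg2rad(angular_res))
  na <- length(angles)
  n_prof <- max(1L, floor(travel / (speed / scan_rate)))
  step <- speed / scan_rate
  dirs1 <- cbind(facing * cos(angles), 0, sin(angles))
  origins <- cbind(origin_xz[1],
                   rep(y_start + (seq_len(n_prof) - 1) * step, each = na),
                   origin_xz[2])
  dirs <- dirs1[rep(seq_len(na), times = n_prof), , drop = FALSE]
  hit <- raycast_cpp(origins, dirs, scene$spheres, scene$rects,
                     scene$cyls, scene$disks)
  rng <- hit$t
  ok <- !is.na(rng)
  rng[ok] <- rng[ok] + rnorm(sum(ok), 0, range_noise)
  refl <- rep(NA_real_, length(rng))
  refl[ok] <- scene$surfaces$refl_mean[hit$id[ok]] +
    rnorm(sum(ok), 0, refl_noise)

  profiles <- vector("list", n_prof)
  for (k in seq_len(n_prof)) {
    sel <- (k - 1) * na + seq_len(na)
    profiles[[k]] <- scan_profile(angles, rng[sel], refl[sel],
                                  index = k - 1)
  }
  pts <- cbind(facing * rng[ok] * cos(angles[((which(ok) - 1) %% na) + 1]),
               origins[ok, 2],
               rng[ok] * sin(angles[((which(ok) - 1) %% na) + 1]))
  pts[, 1] <- pts[, 1] + origin_xz[1]
  pts[, 3] <- pts[, 3] + origin_xz[2]
  list(cloud = point_cloud(pts, reflectance = refl[ok],
                           frame_label = "scanner"),
       ids = hit$id[ok], profiles = profiles)
}

# --- thermal rendering -----------------------------------------------------

#' Render a thermal image of a scene
#'
#' Per-pixel ray casting through the full camera model (distortion
#' inverted per pixel): each pixel receives the truth temperature of the
#' first surface hit, or the background temperature when no surface is
#' hit, plus optional Gaussian pixel noise.
#'
#' @param scene scene to render.
#' @param intrinsics a [camera_intrinsics()].
#' @param cam_pose [rigid_transform()] mapping world to camera frame.
#' @param width,height image size, pixels.
#' @param background no-hit temperature, degrees C.
#' @param pixel_noise per-pixel Gaussian noise SD, degrees C.
#' @return A [thermal_image()].
#' @export
render_thermal_image <- function(scene, intrinsics, cam_pose, width = 640,
                                 height = 480, background = 15,
                                 pixel_noise = 0) {
  px <- cbind(rep(0:(width - 1), times = height),
              rep(0:(height - 1), each = width))
  nxy <- undistort_pixels(intrinsics, px)
  T_cw <- t_inverse(cam_pose)
  centre <- T_cw$t
  dirs <- cbind(nxy[, 1], nxy[, 2], 1) %*% t(T_cw$R)
  origins <- matrix(centre, nrow(dirs), 3, byrow = TRUE)
  hit <- raycast_cpp(origins, dirs, scene$spheres, scene$rects,
                     scene$cyls, scene$disks)
  temp <- rep(background, nrow(dirs))
  ok <- !is.na(hit$id)
  if (any(ok)) {
    pts <- origins[ok, , drop = FALSE] + dirs[ok, , drop = FALSE] *
      hit$t[ok]
    temp[ok] <- scene_temperature_at(scene, hit$id[ok], pts)
  }
  if (pixel_noise > 0) temp <- temp + rnorm(length(temp), 0, pixel_noise)
  thermal_image(matrix(temp, nrow = height, ncol = width, byrow = TRUE))
}

# default rig extrinsics: camera 0.2 m above the scanner, both facing +x.
# Camera axes in scanner coordinates: Z forward (+x), X right (-y),
# Y down (-z).
default_rig_extrinsics <- function(camera_height = 0.2) {
  R <- rbind(c(0, -1, 0), c(0, 0, -1), c(1, 0, 0))
  rigid_transform(R, -as.numeric(R %*% c(0, 0, camera_height)))
}

# --- calibration scene -----------------------------------------------------

#' Simulate a calibration scan (board + thermal frame)
#'
#' Ray-casts the moving line scanner against the heated board (plus floor
#' and back wall clutter) and renders the thermal frame captured at the
#' trigger position: board surface at `board_temp`, Gaussian-plateau hot
#' spots at the projected bulb positions peaking at `bulb_temp`, room
#' background at `ambient`. Defaults reproduce the fused-cloud statistics
#' of the instrument (bulb centres near 46.3 degC on a 21.4 degC board).
#'
#' @param pattern a [pattern_spec()].
#' @param camera a [camera_intrinsics()].
#' @param extrinsics rig extrinsics ([rigid_transform()], scanner frame at
#'   the trigger position to camera).
#' @param board_pose board-to-scanner pose at the trigger position
#'   ([rigid_transform()]); the board z axis should face the scanner.
#' @param noise list with `range` (m) and `pixel` (degC) noise SDs.
#' @param seed RNG seed (full determinism contract).
#' @param travel,speed,scan_rate,angular_res scanner settings.
#' @param trigger_offset travel-axis position of the thermal capture,
#'   metres (default mid-travel).
#' @param board_temp,bulb_temp,ambient scene temperatures, degC.
#' @param bulb_spot_radius effective hot-spot radius on the board, metres.
#' @param width,height image size, pixels.
#' @param clutter include floor and back wall surfaces.
#' @return List with `cloud` (+`ids`), `image`, and `truth` (generating
#'   parameters: board pose, bulb positions in the assembled-cloud frame,
#'   effective cloud-to-camera extrinsics, seed).
#' @export
simulate_calibration_scene <- function(pattern = pattern_spec(),
                                       camera = camera_intrinsics(
                                         570, 570, 320, 240, k1 = -0.1),
                                       extrinsics = default_rig_extrinsics(),
                                       board_pose = NULL,
                                       noise = list(range = 0.005,
                                                    pixel = 0.05),
                                       seed = 1,
                                       travel = 0.8, speed = 0.020,
                                       scan_rate = 25, angular_res = 0.1667,
                                       trigger_offset = NULL,
                                       board_temp = 21.4, bulb_temp = 46.3,
                                       ambient = 15,
                                       bulb_spot_radius = 0.02,
                                       width = 640, height = 480,
                                       clutter = TRUE) {
  set.seed(seed)
  if (is.null(trigger_offset)) trigger_offset <- travel / 2
  if (is.null(board_pose)) {
    # board 1.5 m ahead, roughly facing the scanner, centred mid-travel,
    # raised so the upward 180 degree fan covers it fully
    R <- rot_z(-pi / 2) %*% rot_x(pi / 2) # board z -> -x (toward scanner)
    board_pose <- rigid_transform(R, c(1.5, travel / 2, 0.35))
  }
  scene <- empty_scene()
  xb <- board_pose$R[, 1]; yb <- board_pose$R[, 2]; zb <- board_pose$R[, 3]
  scene <- scene_add_rect(scene, board_pose$t, xb, yb,
                          pattern$board_width / 2,
                          pattern$board_height / 2,
                          class = "board", temp_base = board_temp,
                          refl_mean = 60)
  if (clutter) {
    scene <- scene_add_rect(scene, c(1.25, travel / 2, -0.7),
                            c(1, 0, 0), c(0, 1, 0), 1.25, 3,
                            class = "floor", temp_base = ambient,
                            refl_mean = 30)
    scene <- scene_add_rect(scene, c(2.5, travel / 2, 0.3),
                            c(0, 1, 0), c(0, 0, 1), 3, 1.0,
                            class = "wall", temp_base = ambient,
                            refl_mean = 30)
  }
  if (sum(zb * (c(0, 0, 0) - board_pose$t)) < 0)
    stop("board normal faces away from both sensors")

  scan <- simulate_lidar_scan(scene, travel = travel, speed = speed,
                              scan_rate = scan_rate,
                              angular_res = angular_res,
                              range_noise = noise$range)

  # camera pose in the assembled-cloud frame: rig extrinsics composed
  # with the platform offset at the trigger position
  T_cloud_cam <- t_compose(extrinsics,
                           rigid_transform(diag(3),
                                           c(0, -trigger_offset, 0)))
  img <- render_calibration_image(scene, pattern, camera, T_cloud_cam,
                                  board_pose_cloud = board_pose,
                                  width = width, height = height,
                                  ambient = ambient,
                                  board_temp = board_temp,
                                  bulb_temp = bulb_temp,
                                  bulb_spot_radius = bulb_spot_radius,
                                  pixel_noise = noise$pixel)
  bulbs_cloud <- transform_points(board_pose, pattern_grid(pattern))
  list(cloud = scan$cloud, ids = scan$ids, profiles = scan$profiles,
       image = img,
       truth = list(board_pose = board_pose, bulbs = bulbs_cloud,
                    extrinsics = T_cloud_cam, rig_extrinsics = extrinsics,
                    camera = camera, pattern = pattern, seed = seed,
                    board_temp = board_temp, bulb_temp = bulb_temp))
}

# board at board_temp with Gaussian-plateau bulb hot spots, rest ambient
render_calibration_image <- function(scene, pattern, camera, T_cloud_cam,
                                     board_pose_cloud, width, height,
                                     ambient, board_temp, bulb_temp,
                                     bulb_spot_radius, pixel_noise,
                                     edge_sigma_px = 2) {
  img <- render_thermal_image(scene, camera, T_cloud_cam, width = width,
                              height = height, background = ambient,
                              pixel_noise = 0)
  vals <- img$values
  bulbs <- transform_points(board_pose_cloud, pattern_grid(pattern))
  cam <- transform_points(T_cloud_cam, bulbs)
  if (any(cam[, 3] <= 0)) stop("board outside the camera field of view")
  ctr <- project_point_unchecked(camera, cam)
  r_px <- bulb_spot_radius * camera$fx / cam[, 3]
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), times = width), height, width)
  for (b in seq_len(nrow(ctr))) {
    win <- ceiling(r_px[b] + 5 * edge_sigma_px)
    cx <- round(ctr[b, 1]); cy <- round(ctr[b, 2])
    jx <- max(1, cx + 1 - win):min(width, cx + 1 + win)
    jy <- max(1, cy + 1 - win):min(height, cy + 1 + win)
    if (length(jx) == 0 || length(jy) == 0) next
    d <- sqrt(outer((jy - 1 - ctr[b, 2])^2, (jx - 1 - ctr[b, 1])^2, "+"))
    prof <- board_temp + (bulb_temp - board_temp) *
      exp(-pmax(0, d - r_px[b])^2 / (2 * edge_sigma_px^2))
    vals[jy, jx] <- pmax(vals[jy, jx], prof)
  }
  if (pixel_noise > 0)
    vals <- vals + rnorm(length(vals), 0, pixel_noise)
  thermal_image(vals)
}

#' Synthesize board views for intrinsic calibration
#'
#' Projects the bulb grid through a known camera at randomized board
#' poses, yielding `calibration_view` objects with exact (optionally
#' noisy) feature centres — the parameter-recovery harness for
#' [calibrate_intrinsics()].
#'
#' @param camera generating [camera_intrinsics()].
#' @param pattern a [pattern_spec()].
#' @param n_views number of views.
#' @param pixel_noise Gaussian noise SD added to feature centres, pixels.
#' @param seed RNG seed.
#' @return List with `views` (list of `calibration_view`) and `poses`
#'   (generating board-to-camera [rigid_transform()] per view).
#' @export
simulate_calibration_views <- function(camera, pattern = pattern_spec(),
                                       n_views = 20, pixel_noise = 0,
                                       seed = 1) {
  set.seed(seed)
  grid <- pattern_grid(pattern)
  views <- vector("list", n_views)
  poses <- vector("list", n_views)
  for (i in seq_len(n_views)) {
    R <- rot_z(runif(1, -pi / 12, pi / 12)) %*%
      rot_y(runif(1, -pi / 6, pi / 6)) %*%
      rot_x(runif(1, -pi / 6, pi / 6))
    t <- c(runif(1, -0.15, 0.15), runif(1, -0.1, 0.1), runif(1, 1.2, 1.9))
    pose <- rigid_transform(R, t)
    cam <- transform_points(pose, grid)
    px <- project_point(camera, cam)
    if (pixel_noise > 0)
      px <- px + matrix(rnorm(length(px), 0, pixel_noise), ncol = 2)
    poses[[i]] <- pose
    views[[i]] <- structure(list(features = px, status = "ok",
                                 attempts = 1L, sensitivity = 1L,
                                 range = NULL),
                            class = "calibration_view")
  }
  list(views = views, poses = poses)
}

#' Simulated end-to-end extrinsic calibration study
#'
#' Generates `n_scans` board scans at randomized poses spread over the
#' scanning area (all fully visible to both sensors, as the valid scans
#' of a calibration session are), runs the complete board-location
#' pipeline on each (crop, RANSAC plane with dimension check, PCA +
#' rectangle pose, ICP, bulb positions, staged blob detection), perturbs
#' the detected blob centres with `feature_noise` pixels of Gaussian
#' noise (the residual detector error being studied), solves a per-scan
#' extrinsic candidate, and selects the final solution by cross-scan
#' reprojection RMSE.
#'
#' @param n_scans number of board scans.
#' @param seed RNG seed (drives poses, sensor noise and feature noise).
#' @param camera generating [camera_intrinsics()].
#' @param pattern a [pattern_spec()].
#' @param range_noise LiDAR range noise SD, metres.
#' @param pixel_noise thermal image noise SD, degC.
#' @param feature_noise blob-centre noise SD, pixels.
#' @return List with `solution` (an `extrinsic_solution`), `truth`
#'   (generating cloud-to-camera extrinsics), `rotation_error_deg`,
#'   `translation_error_m`, `per_scan` (board-pose and candidate errors).
#' @export
extrinsic_recovery_study <- function(n_scans = 10, seed = 1,
                                     camera = camera_intrinsics(
                                       570, 570, 320, 240, k1 = -0.1),
                                     pattern = pattern_spec(),
                                     range_noise = 0.005,
                                     pixel_noise = 0.05,
                                     feature_noise = 0.2) {
  set.seed(seed)
  poses <- lapply(seq_len(n_scans), function(i) rigid_transform(
    rot_z(-pi / 2) %*% rot_x(pi / 2) %*%
      (rot_z(runif(1, -0.15, 0.15)) %*% rot_y(runif(1, -0.2, 0.2)) %*%
         rot_x(runif(1, -0.12, 0.12))),
    c(runif(1, 1.35, 1.8), 0.4 + runif(1, -0.07, 0.07),
      runif(1, 0.42, 0.52))))
  scan_seeds <- sample.int(2^30, n_scans)
  jitter_seeds <- sample.int(2^30, n_scans)
  model <- sample_pattern_model(pattern)
  cands <- list(); pairs <- list()
  per_scan <- NULL
  truth <- NULL
  for (i in seq_len(n_scans)) {
    sim <- simulate_calibration_scene(
      pattern = pattern, camera = camera, board_pose = poses[[i]],
      noise = list(range = range_noise, pixel = pixel_noise),
      seed = scan_seeds[i])
    truth <- sim$truth$extrinsics
    cl <- crop_box(sim$cloud, c(0.5, 2.3, -1, 2, -0.1, 1.2))
    plane <- locate_pattern_plane(cl, pattern)
    T_init <- initial_pose_pca(plane$cloud)
    icp <- refine_pose_icp(model, planar_downsample(plane$cloud, 0.01),
                           T_init, max_iter = 30)
    L <- bulb_positions(icp$T_final, pattern)
    view <- staged_blob_detection(sim$image, pattern)
    if (view$status != "ok") stop("blob detection failed on scan ", i)
    set.seed(jitter_seeds[i])
    feats <- view$features +
      matrix(rnorm(2 * pattern$m, 0, feature_noise), ncol = 2)
    cands[[i]] <- solve_extrinsics(feats, L, camera)
    pairs[[i]] <- list(pixels = feats, points = L)
    per_scan <- rbind(per_scan, data.frame(
      scan = i,
      board_rot_err_deg = rotation_angle_deg(icp$T_final, poses[[i]]),
      board_t_err_m = sqrt(sum((icp$T_final$t - poses[[i]]$t)^2)),
      cand_rot_err_deg = rotation_angle_deg(cands[[i]], truth),
      cand_t_err_m = sqrt(sum((cands[[i]]$t - truth$t)^2))))
  }
  sol <- cross_scan_rmse(cands, pairs, camera)
  list(solution = sol, truth = truth,
       rotation_error_deg = rotation_angle_deg(sol$transform, truth),
       translation_error_m = sqrt(sum((sol$transform$t - truth$t)^2)),
       per_scan = per_scan)
}

#' Simulated end-to-end fruit-temperature recovery study
#'
#' Generates the standard synthetic orchard fixture, fuses each side's
#' cloud with its thermal frames (occlusion-aware: the depth buffer is
#' built from the merged two-side cloud), displaces one side by a small
#' known transform and registers it back, runs the full fruit pipeline
#' (stems, tree segments, curvature + reflectance thresholds, clustering,
#' side labels), and scores the result against the generator truth.
#'
#' @param seed RNG seed for the orchard fixture.
#' @param n_trees,fruits_per_tree fixture size.
#' @param match_radius centroid match radius for detection scoring, m.
#' @param ... further arguments to [simulate_orchard_row()].
#' @return List with `detection` (a `detection_report`), `fst_errors`
#'   (per matched fruit, detected minus truth FST mean, degC),
#'   `max_abs_fst_error`, `offset_estimate` (east minus west mean FST of
#'   detected fruits), `offset_truth` (the generating offset),
#'   `offset_se` (standard error of the estimate), `fruits`, `stems`,
#'   `truth`.
#' @export
orchard_recovery_study <- function(seed = 1, n_trees = 5,
                                   fruits_per_tree = 10,
                                   match_radius = 0.06, ...) {
  orc <- simulate_orchard_row(n_trees = n_trees,
                              fruits_per_tree = fruits_per_tree,
                              seed = seed, ...)
  both <- cloud_rbind(orc$sides$east$cloud, orc$sides$west$cloud)
  fuse_side <- function(side) fuse_frames(side$cloud, side$frames,
                                          orc$truth$camera,
                                          zbuffer = TRUE,
                                          buffer_cloud = both)
  fe <- fuse_side(orc$sides$east)
  fw <- fuse_side(orc$sides$west)
  # displace the west side by a known platform-geometry estimate and
  # register it back before merging
  disp <- rigid_transform(rot_z(0.02), c(0.01, -0.015, 0.005))
  al <- align_tree_sides(fe, cloud_transform(fw, t_inverse(disp)),
                         init = disp)
  res <- orchard_fst(al$cloud, n_trees = n_trees)
  ft <- fruit_table(res$fruits)
  tt <- orc$truth$fruits
  det <- detection_f1(as.matrix(ft[, c("x", "y", "z")]),
                      as.matrix(tt[, c("x", "y", "z")]), match_radius)
  mm <- greedy_match(as.matrix(ft[, c("x", "y", "z")]),
                     as.matrix(tt[, c("x", "y", "z")]), match_radius)
  fst_err <- ft$fst_mean[mm[, 1]] - tt$temp[mm[, 2]]
  e <- ft$fst_mean[ft$side == "east"]
  w <- ft$fst_mean[ft$side == "west"]
  list(detection = det, fst_errors = fst_err,
       max_abs_fst_error = if (length(fst_err)) max(abs(fst_err))
         else NA_real_,
       offset_estimate = mean(e) - mean(w),
       offset_truth = orc$truth$temperature_model$east_offset,
       offset_se = sqrt(var(e) / length(e) + var(w) / length(w)),
       fruits = ft, stems = res$stems, truth = orc$truth)
}

# --- metal evaluation frame ------------------------------------------------

#' Default sphere layout for the metal evaluation frame
#'
#' Fifteen spheres (twelve 80 mm, three 60 mm) on five horizontal bars,
#' alternating white barium-sulphate (S_W) and black urethane (S_B)
#' coatings.
#'
#' @param frame_x frame distance from the scanner, metres.
#' @param y_centre frame centre along the travel axis, metres.
#' @return data.frame with columns x, y, z, radius, material.
#' @export
default_sphere_layout <- function(frame_x = 2.0, y_centre = 1.0) {
  heights <- seq(0.5, 1.7, by = 0.3)  # 5 bars at 0.30 m spacing
  offs <- c(-0.55, 0.3, 0.6)          # positions along each bar
  out <- NULL
  k <- 0
  for (h in heights) {
    for (o in offs) {
      k <- k + 1
      out <- rbind(out, data.frame(
        x = frame_x, y = y_centre + o, z = h,
        radius = if (k %% 5 == 0) 0.060 else 0.080,
        material = if (k %% 2 == 0) "S_B" else "S_W"))
    }
  }
  out
}

#' Simulate the metal evaluation tree with sphere targets
#'
#' A 2 m metal trunk carrying five horizontal bars at 0.30 m spacing and
#' coated sphere targets; used to assess the fused temperatures against
#' per-sphere reference values.
#'
#' @param spheres data.frame (x, y, z, radius, material) as from
#'   [default_sphere_layout()].
#' @param temps named per-material temperatures, degC.
#' @param ambient frame/background temperature, degC.
#' @param noise list with `range` (m) and `pixel` (degC) SDs.
#' @param seed RNG seed.
#' @param camera a [camera_intrinsics()].
#' @param travel,speed,scan_rate scanner settings.
#' @return List with `cloud`, `ids`, `image`, `truth` (sphere table with
#'   per-sphere truth temperature, extrinsics, camera).
#' @export
simulate_metal_frame <- function(spheres = default_sphere_layout(),
                                 temps = c(S_W = 19, S_B = 19),
                                 ambient = 19,
                                 noise = list(range = 0.005, pixel = 0.05),
                                 seed = 1,
                                 camera = camera_intrinsics(570, 570,
                                                            320, 240),
                                 travel = 2.2, speed = 0.020,
                                 scan_rate = 25) {
  set.seed(seed)
  d <- as.matrix(dist(spheres[, c("x", "y", "z")]))
  rsum <- outer(spheres$radius, spheres$radius, "+")
  if (any(d[upper.tri(d)] < rsum[upper.tri(rsum)]))
    stop("overlapping spheres in layout")
  frame_x <- spheres$x[1]
  y_c <- mean(spheres$y)
  scene <- empty_scene()
  scene <- scene_add_cylinder(scene, c(frame_x, y_c, 0), c(0, 0, 1),
                              2.0, 0.025, class = "trunk",
                              temp_base = ambient, refl_mean = 55)
  for (h in seq(0.5, 1.7, by = 0.3))
    scene <- scene_add_cylinder(scene, c(frame_x, y_c - 0.65, h),
                                c(0, 1, 0), 1.3, 0.015, class = "bar",
                                temp_base = ambient, refl_mean = 55)
  for (i in seq_len(nrow(spheres))) {
    mat <- spheres$material[i]
    scene <- scene_add_sphere(scene,
                              c(spheres$x[i], spheres$y[i], spheres$z[i]),
                              spheres$radius[i], class = "sphere",
                              temp_base = temps[[mat]],
                              refl_mean = if (mat == "S_W") 90 else 20,
                              material = mat, fruit_id = i)
  }
  scan <- simulate_lidar_scan(scene, travel = travel, speed = speed,
                              scan_rate = scan_rate,
                              range_noise = noise$range)
  # camera behind the scanner line, covering the whole frame
  cam_centre <- c(frame_x - 2.2, y_c, 1.1)
  R <- rbind(c(0, -1, 0), c(0, 0, -1), c(1, 0, 0)) # facing +x
  T_cloud_cam <- rigid_transform(R, -as.numeric(R %*% cam_centre))
  img <- render_thermal_image(scene, camera, T_cloud_cam,
                              background = ambient,
                              pixel_noise = noise$pixel)
  truth_tab <- spheres
  truth_tab$temp <- as.numeric(temps[truth_tab$material])
  truth_tab$sphere_id <- seq_len(nrow(spheres))
  sph_ids <- scene$surfaces$id[scene$surfaces$class == "sphere"]
  list(cloud = scan$cloud, ids = scan$ids, image = img,
       truth = list(spheres = truth_tab, extrinsics = T_cloud_cam,
                    camera = camera, scene = scene,
                    sphere_surface_ids = sph_ids, seed = seed))
}

# --- orchard row -----------------------------------------------------------

#' Simulate a two-sided scan of an apple-tree row
#'
#' Trees along the row axis (y) at `tree_pitch` spacing: vertical trunk
#' cylinders, randomly oriented leaf disks, and spherical fruits placed
#' on the outer canopy of the east (+x) and west (-x) sides. Each side is
#' scanned by the moving line scanner; the thermal camera's 50 Hz stream
#' is represented by one frame per tree, captured as the platform passes
#' it, for fusion with [fuse_frames()]. Fruit surface temperatures carry
#' a configurable east/west offset. Truth labels every point.
#'
#' @param n_trees number of trees.
#' @param tree_pitch along-row tree spacing, metres.
#' @param fruits_per_tree fruits per tree (balanced east/west).
#' @param fruit_radius_range min/max fruit radius, metres.
#' @param leaf_density leaf disks per tree.
#' @param temperature_model list: `fruit`, `leaf`, `trunk` mean degC,
#'   `fruit_sd` per-fruit SD, `east_offset` (east minus west, degC),
#'   `background` (no-hit pixels).
#' @param reflectance_model list of c(mean, sd) per organ:
#'   `fruit`, `leaf`, `trunk` (sensor units).
#' @param noise list: `range` (m), `pixel` (degC), `refl` SDs.
#' @param seed RNG seed.
#' @param camera a [camera_intrinsics()].
#' @param speed,scan_rate scanner settings (orchard platform speed).
#' @param scan_distance scanner line distance from the row axis, metres.
#' @param cam_distance camera distance from the row axis, metres.
#' @return List with `sides` (per side: `cloud`, `ids`, `frames` — each
#'   frame an image + extrinsics + along-row position), `truth` (fruit
#'   table with truth FST, stem positions, inter-side transform `T_ba`
#'   mapping side B points into side A's frame, scene, seed).
#' @export
simulate_orchard_row <- function(n_trees = 5, tree_pitch = 0.95,
                                 fruits_per_tree = 10,
                                 fruit_radius_range = c(0.030, 0.040),
                                 leaf_density = 50,
                                 temperature_model = list(
                                   fruit = 18.5, leaf = 17.5, trunk = 17.8,
                                   fruit_sd = 0.2, east_offset = 0.5,
                                   background = 17.0),
                                 reflectance_model = list(
                                   fruit = c(75, 5), leaf = c(45, 5),
                                   trunk = c(50, 5)),
                                 noise = list(range = 0.005, pixel = 0.1,
                                              refl = 2),
                                 seed = 1,
                                 camera = camera_intrinsics(570, 570,
                                                            320, 240),
                                 speed = 0.10, scan_rate = 25,
                                 scan_distance = 1.8, cam_distance = 1.8) {
  stopifnot(n_trees >= 1, fruits_per_tree >= 1, tree_pitch > 0)
  set.seed(seed)
  tm <- temperature_model; rm <- reflectance_model
  tree_y <- (seq_len(n_trees) - 1) * tree_pitch + 0.6
  scene <- empty_scene()
  fruit_tab <- NULL
  fid <- 0
  for (ti in seq_len(n_trees)) {
    scene <- scene_add_cylinder(scene, c(0, tree_y[ti], 0), c(0, 0, 1),
                                2.2, 0.04, class = "trunk",
                                temp_base = tm$trunk + rnorm(1, 0, 0.1),
                                refl_mean = rnorm(1, rm$trunk[1],
                                                  rm$trunk[2]))
    for (l in seq_len(leaf_density)) {
      # leaf shell kept interior to the fruiting surface: exposed fruits
      # on a slender-spindle wall are largely clear of foliage
      c_l <- c(max(-0.20, min(0.20, rnorm(1, 0, 0.11))),
               tree_y[ti] + runif(1, -0.30, 0.30),
               runif(1, 0.8, 2.1))
      nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
      scene <- scene_add_disk(scene, c_l, nrm, 0.04, class = "leaf",
                              temp_base = tm$leaf + rnorm(1, 0, 0.1),
                              refl_mean = rnorm(1, rm$leaf[1], rm$leaf[2]))
    }
    sides <- rep(c(1, -1), length.out = fruits_per_tree)
    for (f in seq_len(fruits_per_tree)) {
      fid <- fid + 1
      s <- sides[f]
      r <- runif(1, fruit_radius_range[1], fruit_radius_range[2])
      centre <- c(s * runif(1, 0.28, 0.36),
                  tree_y[ti] + runif(1, -0.28, 0.28),
                  runif(1, 0.9, 1.75))
      temp <- tm$fruit + tm$east_offset / 2 * s + rnorm(1, 0, tm$fruit_sd)
      scene <- scene_add_sphere(scene, centre, r, class = "fruit",
                                temp_base = temp, temp_vert = 2,
                                refl_mean = rnorm(1, rm$fruit[1],
                                                  rm$fruit[2]),
                                fruit_id = fid)
      fruit_tab <- rbind(fruit_tab, data.frame(
        fruit_id = fid, tree = ti, x = centre[1], y = centre[2],
        z = centre[3], radius = r, temp = temp,
        side = if (s > 0) "east" else "west"))
    }
  }

  travel <- (n_trees - 1) * tree_pitch + 1.2
  # one thermal frame per tree per side, taken from the 50 Hz stream as
  # the platform passes each tree: keeps the pixel footprint on the
  # fruit small, as the physical rig does
  make_side <- function(facing) {
    scan <- simulate_lidar_scan(scene, travel = travel,
                                origin_xz = c(-facing * scan_distance,
                                              0.7),
                                facing = facing, speed = speed,
                                scan_rate = scan_rate,
                                range_noise = noise$range,
                                refl_noise = noise$refl)
    # camera 0.2 m above the scanner, pitched up so the whole fruiting
    # zone falls inside the vertical field of view
    phi <- 0.25
    R <- if (facing > 0)
      rbind(c(0, -1, 0), c(sin(phi), 0, -cos(phi)),
            c(cos(phi), 0, sin(phi)))
    else
      rbind(c(0, 1, 0), c(-sin(phi), 0, -cos(phi)),
            c(-cos(phi), 0, sin(phi)))
    frames <- lapply(tree_y, function(yc) {
      cam_centre <- c(-facing * cam_distance, yc, 0.9)
      T_row_cam <- rigid_transform(R, -as.numeric(R %*% cam_centre))
      img <- render_thermal_image(scene, camera, T_row_cam,
                                  background = tm$background,
                                  pixel_noise = noise$pixel)
      list(image = img, extrinsics = T_row_cam, y = yc)
    })
    list(scan = scan, frames = frames)
  }
  east <- make_side(-1)  # scanner east of the row, fanning toward -x
  west <- make_side(1)   # scanner west of the row, fanning toward +x

  # side clouds are expressed in the shared row frame; the inter-side
  # transform is therefore the identity by construction, and callers
  # exercising registration displace side B themselves (truth carries the
  # exact transform back).
  sides <- list(
    east = list(cloud = east$scan$cloud, ids = east$scan$ids,
                frames = east$frames),
    west = list(cloud = west$scan$cloud, ids = west$scan$ids,
                frames = west$frames))
  list(sides = sides,
       truth = list(fruits = fruit_tab,
                    stems = cbind(x = rep(0, n_trees), y = tree_y),
                    T_ba = rigid_transform(),
                    scene = scene, camera = camera, seed = seed,
                    temperature_model = tm, tree_pitch = tree_pitch,
                    travel = travel))
}
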