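# Extrinsic LiDAR-to-camera calibration: locate the heated board in the
# 3D cloud (box crop, RANSAC plane, dimension check), estimate its pose
# (PCA initialisation, ICP refinement against a synthetic board model),
# derive the 3D bulb positions, and solve the camera-from-LiDAR pose by
# minimising the reprojection error of the bulb feature pairs. Candidate
# poses from several scans are compared by cross-scan reprojection RMSE.

#' Crop a point cloud with an axis-aligned box
#'
#' Used to remove floor, ceiling and walls so the largest remaining plane
#' is the calibration board. Only points strictly inside the bounds are
#' retained; per-point attributes are carried along.
#'
#' @param cloud a [point_cloud()].
#' @param bounds numeric vector `c(xmin, xmax, ymin, ymax, zmin, zmax)`,
#'   metres.
#' @return The cropped [point_cloud()] (a warning is emitted when empty).
#' @export
crop_box <- function(cloud, bounds) {
  bounds <- as.numeric(bounds)
  stopifnot(length(bounds) == 6)
  if (any(bounds[c(1, 3, 5)] >= bounds[c(2, 4, 6)]))
    stop("invalid box: each min must be below its max")
  p <- cloud$points
  keep <- p[, 1] > bounds[1] & p[, 1] < bounds[2] &
    p[, 2] > bounds[3] & p[, 2] < bounds[4] &
    p[, 3] > bounds[5] & p[, 3] < bounds[6]
  if (!any(keep)) warning("crop_box: no points inside bounds")
  cloud_subset(cloud, keep)
}

#' Locate the calibration-board plane by RANSAC
#'
#' Extracts the largest-consensus plane from a (pre-cropped) cloud and
#' verifies that the inlier set's oriented bounding box matches the board
#' dimensions within `dim_tolerance`, rejecting scans where the board is
#' cut off.
#'
#' @param cloud a [point_cloud()] in which the board is the biggest plane.
#' @param pattern a [pattern_spec()].
#' @param ransac_threshold inlier distance threshold, metres.
#' @param dim_tolerance fractional tolerance on the board extents.
#' @param iterations RANSAC iterations.
#' @param min_inliers minimum consensus size.
#' @return List with `cloud` (inlier [point_cloud()]), `inliers` (indices),
#'   `normal`, `offset` (plane `n . p = offset`), `extents` (measured
#'   in-plane extents, metres).
#' @export
locate_pattern_plane <- function(cloud, pattern, ransac_threshold = 0.010,
                                 dim_tolerance = 0.10, iterations = 1000,
                                 min_inliers = 500) {
  p <- cloud$points
  n <- nrow(p)
  if (n < 3) stop("plane not found: fewer than 3 points")
  best <- NULL
  best_count <- 0
  for (it in seq_len(iterations)) {
    s <- sample.int(n, 3)
    v1 <- p[s[2], ] - p[s[1], ]
    v2 <- p[s[3], ] - p[s[1], ]
    nv <- cross3(v1, v2)
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-12) next
    nv <- nv / nn
    d <- abs(as.numeric(p %*% nv) - sum(nv * p[s[1], ]))
    count <- sum(d < ransac_threshold)
    if (count > best_count) {
      best_count <- count
      best <- nv
      best_off <- sum(nv * p[s[1], ])
    }
  }
  if (is.null(best) || best_count < min_inliers)
    stop("plane not found: best consensus ", best_count,
         " below minimum ", min_inliers)
  # least-squares refit on the consensus set, then re-collect inliers
  for (pass in 1:2) {
    d <- abs(as.numeric(p %*% best) - best_off)
    idx <- which(d < ransac_threshold)
    ctr <- colMeans(p[idx, , drop = FALSE])
    ev <- eigen(crossprod(sweep(p[idx, , drop = FALSE], 2, ctr)),
                symmetric = TRUE)
    best <- ev$vectors[, 3]
    best_off <- sum(best * ctr)
  }
  # oriented extents from the minimum-area enclosing rectangle of the
  # in-plane projection (tail-trimmed so range-noise smear at oblique
  # incidence does not inflate the measured dimensions)
  q2 <- sweep(p[idx, , drop = FALSE], 2, ctr) %*% ev$vectors[, 1:2]
  exts <- min_area_rect(q2)$extents
  dims <- sort(c(pattern$board_width, pattern$board_height),
               decreasing = TRUE)
  if (any(abs(exts - dims) > dim_tolerance * dims))
    stop(sprintf(
      "board dimension mismatch: measured %.3f x %.3f m, expected %.3f x %.3f m",
      exts[1], exts[2], dims[1], dims[2]))
  list(cloud = cloud_subset(cloud, idx), inliers = idx, normal = best,
       offset = best_off, extents = exts)
}

#' Downsample a near-planar cloud on an in-plane voxel grid
#'
#' Lays the voxel grid in the cloud's own best-fit plane and replaces
#' each occupied cell by the centroid of its points. Unlike a cubic
#' grid, this equalises the range-dependent scan density across the
#' board, which would otherwise bias the pose estimates.
#'
#' @param cloud a near-planar [point_cloud()] (the located board).
#' @param voxel cell size, metres.
#' @return The downsampled [point_cloud()].
#' @export
planar_downsample <- function(cloud, voxel = 0.010) {
  stopifnot(voxel > 0)
  p0 <- cloud$points
  if (nrow(p0) < 3) stop("degenerate plane cloud: too few points")
  ctr0 <- colMeans(p0)
  ev0 <- eigen(crossprod(sweep(p0, 2, ctr0)) / nrow(p0), symmetric = TRUE)
  if (ev0$values[2] < 1e-12 * ev0$values[1])
    stop("degenerate plane cloud: points are collinear")
  q <- sweep(p0, 2, ctr0) %*% ev0$vectors[, 1:2]
  key <- paste(floor(q[, 1] / voxel), floor(q[, 2] / voxel))
  grp <- match(key, unique(key))
  point_cloud(rowsum(p0, grp) / tabulate(grp),
              frame_label = cloud$frame_label)
}

# minimum-area enclosing rectangle of 2D points (rotating calipers over
# convex-hull edges); returns unit long/short axes, trimmed extents and
# the rectangle angle
min_area_rect <- function(q, trim = 0.001) {
  h <- grDevices::chull(q)
  hp <- q[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3) stop("degenerate 2D point set")
  best <- NULL
  for (e in seq_len(nh)) {
    v <- hp[e %% nh + 1, ] - hp[e, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    ax <- v / nv
    R2 <- cbind(ax, c(-ax[2], ax[1]))
    r <- hp %*% R2
    ext <- c(diff(range(r[, 1])), diff(range(r[, 2])))
    if (is.null(best) || prod(ext) < best$area)
      best <- list(area = prod(ext), R2 = R2)
  }
  r_all <- q %*% best$R2
  ext <- c(diff(quantile(r_all[, 1], c(trim, 1 - trim))),
           diff(quantile(r_all[, 2], c(trim, 1 - trim))))
  if (ext[1] >= ext[2])
    list(long = best$R2[, 1], short = best$R2[, 2],
         extents = c(ext[1], ext[2]))
  else
    list(long = best$R2[, 2], short = best$R2[, 1],
         extents = c(ext[2], ext[1]))
}

#' Initial board pose from principal component analysis
#'
#' Downsamples the located plane points on a voxel grid laid in the board
#' plane (equalising the range-dependent scan density, which would
#' otherwise bias the axes). The board normal is the smallest-eigenvalue
#' eigenvector of the centred covariance; the in-plane axes come from the
#' minimum-area enclosing rectangle of the projected points (for a board
#' with a 0.5/0.6 aspect the in-plane covariance eigengap is so small
#' that the raw PCA axes swing by degrees under sampling perturbations,
#' while the board's own edges pin the rectangle orientation). The
#' centroid is the origin. Signs follow a fixed convention: the normal
#' faces the sensor origin and the long axis (board height) has positive
#' dot product with the up vector.
#'
#' @param plane_cloud [point_cloud()] of board plane points.
#' @param voxel downsampling voxel size, metres.
#' @param sensor_origin scanner origin used to orient the normal.
#' @param up up direction used to orient the long axis.
#' @return A [rigid_transform()] mapping board frame to scanner frame
#'   (`T_initial`).
#' @export
initial_pose_pca <- function(plane_cloud, voxel = 0.010,
                             sensor_origin = c(0, 0, 0), up = c(0, 0, 1)) {
  ds <- planar_downsample(plane_cloud, voxel)
  p <- ds$points
  if (nrow(p) < 3) stop("degenerate plane cloud: too few points")
  ctr <- colMeans(p)
  ev <- eigen(crossprod(sweep(p, 2, ctr)) / nrow(p), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * ev$values[1])
    stop("degenerate plane cloud: points are collinear")
  zb <- ev$vectors[, 3] # normal
  e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
  rect <- min_area_rect(sweep(p, 2, ctr) %*% cbind(e1, e2))
  yb <- rect$long[1] * e1 + rect$long[2] * e2 # long axis (board height)
  if (sum(zb * (sensor_origin - ctr)) < 0) zb <- -zb
  if (sum(yb * up) < 0) yb <- -yb
  yb <- yb - sum(yb * zb) * zb # exact orthogonality
  yb <- yb / sqrt(sum(yb^2))
  xb <- cross3(yb, zb)
  rigid_transform(cbind(xb, yb, zb), ctr)
}

#' Synthetic board model cloud
#'
#' Uniform grid over the board rectangle in the board frame (Z = 0),
#' serving as the perfect model registered onto the measured plane.
#'
#' @param pattern a [pattern_spec()].
#' @param resolution grid step, metres.
#' @return A [point_cloud()] in the board frame.
#' @export
sample_pattern_model <- function(pattern, resolution = 0.005) {
  stopifnot(resolution > 0)
  xs <- seq(-pattern$board_width / 2, pattern$board_width / 2,
            by = resolution)
  ys <- seq(-pattern$board_height / 2, pattern$board_height / 2,
            by = resolution)
  point_cloud(cbind(rep(xs, times = length(ys)),
                    rep(ys, each = length(xs)), 0),
              frame_label = "board")
}

#' Refine a board pose by iterative closest point
#'
#' Point-to-point ICP registering the synthetic board `model` onto the
#' measured `data`, starting from `T_initial`. Returns the correction
#' `T_corr` expressed in the board frame and the final pose
#' `T_final = T_initial o T_corr`.
#'
#' @param model board-frame [point_cloud()] from [sample_pattern_model()].
#' @param data scanner-frame [point_cloud()] of board points.
#' @param T_initial initial pose ([rigid_transform()], board to scanner).
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the RMS correspondence distance.
#' @return List with `T_corr`, `T_final`, `converged`, `mean_dist` (final
#'   mean correspondence distance, metres) and `history` (per-iteration
#'   RMS correspondence distances — the quantity ICP provably never
#'   increases).
#' @export
refine_pose_icp <- function(model, data, T_initial, max_iter = 50,
                            tol = 1e-9) {
  M <- model$points
  D <- data$points
  T_cur <- T_initial
  history <- numeric(0)
  mean_dist <- NA_real_
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mt <- transform_points(T_cur, M)
    nn <- nn1_points(D, Mt)
    history <- c(history, sqrt(mean(nn$dist^2)))
    mean_dist <- mean(nn$dist)
    T_cur <- fit_rigid(M, D[nn$idx, , drop = FALSE])
    if (abs(prev - history[it]) < tol) { converged <- TRUE; break }
    prev <- history[it]
  }
  if (!converged)
    warning("refine_pose_icp: not converged after ", max_iter,
            " iterations")
  T_final <- T_cur
  T_corr <- t_compose(t_inverse(T_initial), T_final)
  list(T_corr = T_corr, T_final = T_final, converged = converged,
       mean_dist = mean_dist, history = history)
}

#' Bulb positions in scanner coordinates
#'
#' Maps the m board-frame grid positions through the final board pose,
#' in canonical grid order (matching [sort_blobs_grid()] output).
#'
#' @param T_final board-to-scanner pose ([rigid_transform()]).
#' @param pattern a [pattern_spec()].
#' @return m x 3 matrix of bulb positions, metres.
#' @export
bulb_positions <- function(T_final, pattern) {
  out <- transform_points(T_final, pattern_grid(pattern))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Solve the camera-from-LiDAR extrinsics from feature pairs
#'
#' Minimises the reprojection error of the paired 2D blob centres and 3D
#' bulb positions over the rigid camera-from-LiDAR transform, with the
#' intrinsics held fixed. Planar configurations (the board case) are
#' initialised from a plane homography, general configurations from a
#' direct linear transform; both are refined by Levenberg-Marquardt.
#'
#' @param pixels m x 2 matrix of feature pixel coordinates (canonical
#'   grid order).
#' @param points m x 3 matrix of the corresponding LiDAR-frame positions.
#' @param intrinsics a [camera_intrinsics()].
#' @return A [rigid_transform()] mapping LiDAR to camera coordinates.
#' @export
solve_extrinsics <- function(pixels, points, intrinsics) {
  pixels <- as.matrix(pixels)
  points <- as_points_matrix(points)
  m <- nrow(points)
  if (m < 6 || nrow(pixels) != m)
    stop("insufficient data: need at least 6 feature pairs, got ", m)
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))$d
  if (sv[2] < 1e-9 * sv[1])
    stop("degenerate geometry: 3D features are collinear")
  planar <- sv[3] < 1e-6 * sv[1]
  norm_xy <- undistort_pixels(intrinsics, pixels)

  if (planar) {
    ev <- eigen(crossprod(sweep(points, 2, ctr)), symmetric = TRUE)
    e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
    q <- cbind(sweep(points, 2, ctr) %*% e1, sweep(points, 2, ctr) %*% e2)
    H <- fit_homography(q, norm_xy)
    h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
    lam <- 1 / sqrt(sum(h1^2))
    if (lam * h3[3] < 0) lam <- -lam
    Rpc <- nearest_rotation(cbind(lam * h1, lam * h2,
                                  cross3(lam * h1, lam * h2)))
    T_pc <- rigid_transform(Rpc, lam * h3, check = FALSE)
    T_pl <- rigid_transform(cbind(e1, e2, cross3(e1, e2)), ctr,
                            check = FALSE)
    T0 <- t_compose(T_pc, t_inverse(T_pl))
  } else {
    # DLT on normalized coordinates for [R|t]
    A <- matrix(0, 2 * m, 12)
    X <- cbind(points, 1)
    A[seq(1, 2 * m, 2), 1:4] <- -X
    A[seq(1, 2 * m, 2), 9:12] <- norm_xy[, 1] * X
    A[seq(2, 2 * m, 2), 5:8] <- -X
    A[seq(2, 2 * m, 2), 9:12] <- norm_xy[, 2] * X
    sol <- svd(A)$v[, 12]
    P <- matrix(sol, 3, 4, byrow = TRUE)
    Mrot <- P[, 1:3]
    dM <- det(Mrot)
    sc <- sign(dM) * abs(dM)^(1 / 3) # sign-preserving cube-root scale
    if (!is.finite(sc) || sc == 0) sc <- mean(svd(Mrot)$d)
    P <- P / sc
    # cheirality: features must be in front of the camera
    if (mean(cbind(points, 1) %*% P[3, ] > 0) < 0.5) P <- -P
    T0 <- rigid_transform(nearest_rotation(P[, 1:3]), P[, 4],
                          check = FALSE)
  }

  residual <- function(par) {
    R <- rodrigues_to_matrix(par[1:3])
    cam <- sweep(points %*% t(R), 2, par[4:6], "+")
    cam[, 3] <- pmax(cam[, 3], 1e-9)
    as.numeric(project_point_unchecked(intrinsics, cam) - pixels)
  }
  par0 <- c(matrix_to_rodrigues(T0$R), T0$t)
  fit <- minpack.lm::nls.lm(par0, fn = residual,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  rigid_transform(rodrigues_to_matrix(fit$par[1:3]), fit$par[4:6])
}

#' Cross-scan reprojection RMSE and candidate selection
#'
#' Evaluates each candidate extrinsic transform against the feature pairs
#' of every valid scan: `rmse = sqrt(sum_ij ||m'_ij - m_ij||^2 / (N M))`
#' over N scans of M points. The element-wise mean of all candidate
#' parameters (rotation averaged then projected back onto SO(3)) is also
#' evaluated; the transform with the minimal RMSE is marked selected.
#'
#' @param candidates list of [rigid_transform()] candidates.
#' @param scans list of scans, each a list with `pixels` (M x 2) and
#'   `points` (M x 3) in matched order.
#' @param intrinsics a [camera_intrinsics()].
#' @return An object of class `extrinsic_solution`: list with `transform`
#'   (selected), `rmse`, `per_candidate_rmse`, `mean_candidate`,
#'   `mean_candidate_rmse`, `selected` (index or `"mean"`).
#' @export
cross_scan_rmse <- function(candidates, scans, intrinsics) {
  stopifnot(length(candidates) >= 1, length(scans) >= 1)
  eval_rmse <- function(T) {
    ss <- 0; npts <- 0
    for (sc in scans) {
      cam <- transform_points(T, sc$points)
      cam[, 3] <- pmax(cam[, 3], 1e-9)
      proj <- project_point_unchecked(intrinsics, cam)
      ss <- ss + sum((proj - as.matrix(sc$pixels))^2)
      npts <- npts + nrow(sc$points)
    }
    sqrt(ss / npts)
  }
  per <- vapply(candidates, eval_rmse, 0)
  Rm <- nearest_rotation(Reduce(`+`, lapply(candidates, `[[`, "R")) /
                           length(candidates))
  tm <- Reduce(`+`, lapply(candidates, `[[`, "t")) / length(candidates)
  mean_cand <- rigid_transform(Rm, tm)
  mean_rmse <- eval_rmse(mean_cand)
  all_rmse <- c(per, mean_rmse)
  best <- which.min(all_rmse)
  selected <- if (best > length(candidates)) "mean" else best
  transform <- if (identical(selected, "mean")) mean_cand
    else candidates[[best]]
  structure(list(transform = transform, rmse = all_rmse[best],
                 per_candidate_rmse = per, mean_candidate = mean_cand,
                 mean_candidate_rmse = mean_rmse, selected = selected),
            class = "extrinsic_solution")
}

#' @export
print.extrinsic_solution <- function(x, ...) {
  cat(sprintf(
    "Extrinsic solution: selected %s (RMSE %.4f px; mean candidate %.4f px)\n",
    if (identical(x$selected, "mean")) "element-wise mean"
    else paste("scan", x$selected), x$rmse, x$mean_candidate_rmse))
  print(x$transform)
  invisible(x)
}

#' Full extrinsic calibration from board scans
#'
#' Runs the board-location pipeline on each scan (crop, RANSAC plane with
#' dimension check, PCA pose, ICP refinement, bulb positions), pairs the
#' bulbs with the staged blob detection on the scan's thermal image,
#' solves a per-scan candidate extrinsic, and selects the final transform
#' by cross-scan reprojection RMSE. Scans whose board is cut off or whose
#' image fails blob detection are reported as invalid, never silently
#' dropped.
#'
#' @param scans list of scans, each a list with `cloud` ([point_cloud()])
#'   and `image` ([thermal_image()]).
#' @param intrinsics a [camera_intrinsics()].
#' @param pattern a [pattern_spec()].
#' @param crop optional crop bounds passed to [crop_box()].
#' @param ransac_threshold,dim_tolerance,voxel,model_resolution pipeline
#'   parameters (metres / fraction).
#' @param min_inliers minimum RANSAC consensus.
#' @param presets blob-detector presets for [staged_blob_detection()].
#' @return List with `solution` (an `extrinsic_solution`), `report`
#'   (per-scan data.frame: valid, reason, rmse), `scan_pairs`.
#' @export
calibrate_extrinsics <- function(scans, intrinsics, pattern, crop = NULL,
                                 ransac_threshold = 0.010,
                                 dim_tolerance = 0.10, voxel = 0.010,
                                 model_resolution = 0.005,
                                 min_inliers = 500,
                                 presets = default_presets()) {
  model <- sample_pattern_model(pattern, model_resolution)
  candidates <- list()
  pairs <- list()
  status <- character(length(scans))
  reason <- character(length(scans))
  for (i in seq_along(scans)) {
    res <- tryCatch({
      cl <- scans[[i]]$cloud
      if (!is.null(crop)) cl <- crop_box(cl, crop)
      plane <- locate_pattern_plane(cl, pattern,
                                    ransac_threshold = ransac_threshold,
                                    dim_tolerance = dim_tolerance,
                                    min_inliers = min_inliers)
      T_init <- initial_pose_pca(plane$cloud, voxel = voxel)
      icp <- refine_pose_icp(model, planar_downsample(plane$cloud, voxel),
                             T_init)
      L <- bulb_positions(icp$T_final, pattern)
      view <- staged_blob_detection(scans[[i]]$image, pattern,
                                    presets = presets)
      if (view$status != "ok") stop("blob detection failed")
      cand <- solve_extrinsics(view$features, L, intrinsics)
      list(cand = cand, pair = list(pixels = view$features, points = L))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- "invalid"
      reason[i] <- conditionMessage(res)
    } else {
      status[i] <- "valid"
      reason[i] <- ""
      candidates[[length(candidates) + 1]] <- res$cand
      pairs[[length(pairs) + 1]] <- res$pair
    }
  }
  if (length(candidates) == 0)
    stop("no valid scans: extrinsic calibration impossible")
  sol <- cross_scan_rmse(candidates, pairs, intrinsics)
  per_rmse <- rep(NA_real_, length(scans))
  per_rmse[status == "valid"] <- sol$per_candidate_rmse
  list(solution = sol,
       report = data.frame(scan = seq_along(scans), status = status,
                           reason = reason, rmse = per_rmse),
       scan_pairs = pairs)
}
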