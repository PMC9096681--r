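# Intrinsic calibration of the thermal camera from an actively heated
# lightbulb board: staged multi-threshold blob detection on the 8-bit
# rescaled image, canonical grid ordering, and minimisation of the
# reprojection error over camera matrix, distortion and per-view poses.

#' Camera intrinsics (pinhole + radial/tangential distortion)
#'
#' Focal lengths and principal point in pixels (camera matrix A) plus
#' radial (k1, k2, k3) and tangential (p1, p2) distortion coefficients.
#'
#' @param fx,fy focal lengths, pixels.
#' @param cx,cy principal point, pixels.
#' @param k1,k2,k3 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, k1 = 0, k2 = 0, k3 = 0,
                              p1 = 0, p2 = 0) {
  stopifnot(fx > 0, fy > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Camera intrinsics: fx %.2f fy %.2f cx %.2f cy %.2f px\n",
              x$fx, x$fy, x$cx, x$cy))
  cat(sprintf("  distortion: k1 %.4g k2 %.4g k3 %.4g p1 %.4g p2 %.4g\n",
              x$k1, x$k2, x$k3, x$p1, x$p2))
  invisible(x)
}

#' Calibration pattern geometry
#'
#' The heated board: lightbulbs on a regular grid, board dimensions in
#' metres. Defaults match a 0.5 x 0.6 m board with 30 bulbs in a 5 x 6
#' grid at 100 mm spacing.
#'
#' @param rows,cols grid dimensions (rows x cols = m bulbs).
#' @param spacing bulb spacing, metres.
#' @param board_width,board_height board dimensions, metres.
#' @param bulb_diameter bulb diameter, metres.
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(rows = 5, cols = 6, spacing = 0.100,
                         board_width = 0.500, board_height = 0.600,
                         bulb_diameter = 0.004) {
  stopifnot(rows >= 2, cols >= 2, spacing > 0)
  if ((cols - 1) * spacing > board_width + 1e-9 ||
      (rows - 1) * spacing > board_height + 1e-9)
    stop("bulb grid does not fit inside the board")
  structure(list(rows = rows, cols = cols, spacing = spacing,
                 board_width = board_width, board_height = board_height,
                 bulb_diameter = bulb_diameter,
                 m = as.integer(rows * cols)),
            class = "pattern_spec")
}

#' Bulb positions in the board frame
#'
#' Canonical row-major order (top-left first as seen from the sensor
#' side). Board frame: x along the board width (viewer's right), y along
#' the height (up), z the normal toward the sensor; origin at the board
#' centre.
#'
#' @param pattern a [pattern_spec()].
#' @return m x 3 matrix of bulb coordinates (Z = 0), metres.
#' @export
pattern_grid <- function(pattern) {
  i <- rep(seq_len(pattern$rows), each = pattern$cols)  # row, top first
  j <- rep(seq_len(pattern$cols), times = pattern$rows) # col, left first
  x <- ((j - 1) - (pattern$cols - 1) / 2) * pattern$spacing
  y <- ((pattern$rows - 1) / 2 - (i - 1)) * pattern$spacing
  cbind(x = x, y = y, z = 0)
}

#' Temperature range for 8-bit conversion
#' @param low,high range bounds, degrees C (`low < high`).
#' @return An object of class `temperature_range`.
#' @export
temperature_range <- function(low, high) {
  if (!(low < high)) stop("degenerate temperature range: low must be < high")
  structure(list(low = low, high = high), class = "temperature_range")
}

#' Blob-detector sensitivity preset
#'
#' Multi-threshold sweep parameters: binary slices from `minThreshold` to
#' `maxThreshold` in `thresholdStep` increments, components kept when
#' their area lies in `[minArea, maxArea]` pixels.
#'
#' @param id preset id (1, 2 or 3).
#' @param minThreshold,maxThreshold,thresholdStep 8-bit threshold sweep.
#' @param minArea,maxArea component area bounds, pixels^2.
#' @return An object of class `sensitivity_preset`.
#' @export
sensitivity_preset <- function(id, minThreshold, maxThreshold,
                               thresholdStep, minArea, maxArea) {
  stopifnot(minThreshold >= 0, minThreshold < maxThreshold,
            maxThreshold <= 255, thresholdStep >= 1,
            minArea > 0, minArea <= maxArea)
  structure(list(id = id, minThreshold = minThreshold,
                 maxThreshold = maxThreshold, thresholdStep = thresholdStep,
                 minArea = minArea, maxArea = maxArea),
            class = "sensitivity_preset")
}

#' Default sensitivity presets
#'
#' Preset 1 is the published parameter set (20, 220, 15, 160, 230).
#' Presets 2 and 3 are package defaults that progressively widen the area
#' band and refine the threshold step, used as fallbacks by
#' [staged_blob_detection()].
#'
#' @return List of three [sensitivity_preset()] objects.
#' @export
default_presets <- function() {
  list(sensitivity_preset(1, 20, 220, 15, 160, 230),
       sensitivity_preset(2, 20, 220, 15, 80, 350),
       sensitivity_preset(3, 20, 220, 5, 20, 600))
}

#' Rescale a thermal image to 8 bit over a temperature range
#'
#' `v` maps to `round(255 * clip((v - low)/(high - low), 0, 1))` with
#' deterministic half-up rounding. Narrowing the range (raising `low`)
#' increases the contrast of hot blobs against the cooler board.
#'
#' @param image a [thermal_image()].
#' @param range a [temperature_range()].
#' @return Integer matrix (height x width) with values in 0..255.
#' @export
scale_to_8bit <- function(image, range) {
  stopifnot(inherits(range, "temperature_range"))
  u <- (image$values - range$low) / (range$high - range$low)
  u[u < 0] <- 0
  u[u > 1] <- 1
  out <- round_half_up(255 * u)
  storage.mode(out) <- "integer"
  out
}

#' Detect bright blobs in an 8-bit image
#'
#' Multi-threshold sweep: the image is binarised at each threshold from
#' `minThreshold` to `maxThreshold` in `thresholdStep` increments; bright
#' connected components (8-connectivity) with area inside
#' `[minArea, maxArea]` are extracted per slice, and components whose
#' centres fall within `merge_dist` across slices are grouped into one
#' blob (centre = mean of grouped centres, radius = mean equivalent
#' radius). A blob must appear in at least `min_repeatability` slices.
#'
#' @param image8 integer matrix in 0..255 (from [scale_to_8bit()]).
#' @param preset a [sensitivity_preset()].
#' @param merge_dist cross-threshold grouping distance, pixels.
#' @param min_repeatability minimum number of supporting slices.
#' @return data.frame with columns `x`, `y` (0-based pixel centres,
#'   sub-pixel), `radius`, `area`, ordered by `y` then `x`.
#' @export
detect_blobs <- function(image8, preset, merge_dist = 10,
                         min_repeatability = 2) {
  stopifnot(inherits(preset, "sensitivity_preset"))
  thresholds <- seq(preset$minThreshold, preset$maxThreshold,
                    by = preset$thresholdStep)
  centers <- list()
  for (th in thresholds) {
    bin <- matrix(as.integer(image8 > th), nrow(image8), ncol(image8))
    lab <- cc_label8(bin)
    if (max(lab) == 0) next
    keep <- which(lab > 0)
    l <- lab[keep]
    area <- tabulate(l)
    ok <- which(area >= preset$minArea & area <= preset$maxArea)
    if (length(ok) == 0) next
    # pixel coordinates: x = col - 1, y = row - 1
    rw <- (keep - 1) %% nrow(image8)
    cl <- (keep - 1) %/% nrow(image8)
    cx <- rowsum(cl, l)[, 1] / area
    cy <- rowsum(rw, l)[, 1] / area
    centers[[length(centers) + 1]] <-
      data.frame(x = cx[ok], y = cy[ok], area = area[ok],
                 radius = sqrt(area[ok] / pi))
  }
  groups <- list() # running blob groups across slices
  for (slice in centers) {
    for (i in seq_len(nrow(slice))) {
      assigned <- FALSE
      if (length(groups)) {
        gx <- vapply(groups, function(g) g$x / g$n, 0)
        gy <- vapply(groups, function(g) g$y / g$n, 0)
        d <- sqrt((gx - slice$x[i])^2 + (gy - slice$y[i])^2)
        j <- which.min(d)
        if (d[j] < merge_dist) {
          g <- groups[[j]]
          groups[[j]] <- list(x = g$x + slice$x[i], y = g$y + slice$y[i],
                              area = g$area + slice$area[i],
                              radius = g$radius + slice$radius[i],
                              n = g$n + 1)
          assigned <- TRUE
        }
      }
      if (!assigned)
        groups[[length(groups) + 1]] <-
          list(x = slice$x[i], y = slice$y[i], area = slice$area[i],
               radius = slice$radius[i], n = 1)
    }
  }
  groups <- Filter(function(g) g$n >= min_repeatability, groups)
  if (length(groups) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      radius = numeric(0), area = numeric(0)))
  out <- data.frame(
    x = vapply(groups, function(g) g$x / g$n, 0),
    y = vapply(groups, function(g) g$y / g$n, 0),
    radius = vapply(groups, function(g) g$radius / g$n, 0),
    area = vapply(groups, function(g) g$area / g$n, 0))
  out[order(out$y, out$x), , drop = FALSE]
}

#' Staged blob detection on a thermal image
#'
#' Implements the escalation loop: the image is scaled to its full
#' temperature range and the blob detector applied with each sensitivity
#' preset in order; success means exactly `m = rows * cols` blobs. When
#' all presets fail, the lower bound of the temperature range is raised
#' by `range_step` degrees and the sweep repeated, up to `n_ranges`
#' ranges. After `n_ranges x 3` failed attempts the view is discarded.
#'
#' @param image a [thermal_image()].
#' @param pattern a [pattern_spec()].
#' @param presets list of three [sensitivity_preset()] (ordered s = 1..3).
#' @param n_ranges number of temperature ranges to try.
#' @param range_step lower-bound increment per range, degrees C.
#' @param merge_dist cross-threshold grouping distance, pixels.
#' @return An object of class `calibration_view`: list with `features`
#'   (m x 2 matrix of sorted blob centres, canonical grid order, or NULL),
#'   `status` (`"ok"` or `"discarded"`), `attempts`, `sensitivity`,
#'   `range` used.
#' @export
staged_blob_detection <- function(image, pattern,
                                  presets = default_presets(),
                                  n_ranges = 4, range_step = 5,
                                  merge_dist = 10) {
  stopifnot(inherits(image, "thermal_image"), inherits(pattern, "pattern_spec"))
  lo <- min(image$values)
  hi <- max(image$values)
  attempts <- 0L
  for (r in seq_len(n_ranges)) {
    rng_lo <- lo + (r - 1) * range_step
    if (rng_lo >= hi) break
    rng <- temperature_range(rng_lo, hi)
    img8 <- scale_to_8bit(image, rng)
    for (s in seq_along(presets)) {
      attempts <- attempts + 1L
      blobs <- detect_blobs(img8, presets[[s]], merge_dist = merge_dist)
      if (nrow(blobs) == pattern$m) {
        feats <- tryCatch(
          sort_blobs_grid(as.matrix(blobs[, c("x", "y")]), pattern),
          error = function(e) NULL)
        if (!is.null(feats)) {
          return(structure(list(features = feats, status = "ok",
                                attempts = attempts,
                                sensitivity = presets[[s]]$id,
                                range = c(rng$low, rng$high)),
                           class = "calibration_view"))
        }
      }
    }
  }
  structure(list(features = NULL, status = "discarded",
                 attempts = attempts, sensitivity = NA_integer_,
                 range = NULL),
            class = "calibration_view")
}

#' @export
print.calibration_view <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf(
      "Calibration view: ok (%d features, sensitivity %d, %d attempts)\n",
      nrow(x$features), x$sensitivity, x$attempts))
  else
    cat(sprintf("Calibration view: discarded after %d attempts\n",
                x$attempts))
  invisible(x)
}

#' Sort detected blobs into canonical grid order
#'
#' Projects the blob constellation onto its two principal axes, splits it
#' into `rows` groups along the minor axis (rows are stacked along the
#' short side of the grid) at the largest gaps, and sorts within each row
#' along the dominant axis. Axis signs follow the image axes (dominant
#' axis rightward, minor axis downward), so the output is row-major from
#' the top-left and invariant to in-plane rotations up to +/- 30 degrees.
#'
#' @param blobs m x 2 matrix of blob centres (pixels), m = rows * cols.
#' @param pattern a [pattern_spec()].
#' @return m x 2 matrix in canonical grid order.
#' @export
sort_blobs_grid <- function(blobs, pattern) {
  blobs <- as.matrix(blobs)
  if (nrow(blobs) != pattern$m)
    stop("expected exactly ", pattern$m, " blobs, got ", nrow(blobs))
  ctr <- sweep(blobs, 2, colMeans(blobs))
  ev <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)
  e1 <- ev$vectors[, 1] # dominant: along-row direction (cols levels)
  e2 <- ev$vectors[, 2] # minor: across rows
  if (e1[1] < 0) e1 <- -e1 # rightward in image coordinates
  if (e2[2] < 0) e2 <- -e2 # downward in image coordinates
  u <- ctr %*% e1
  v <- ctr %*% e2
  ord <- order(v)
  vs <- v[ord]
  gaps <- diff(vs)
  cut_at <- sort(order(gaps, decreasing = TRUE)[seq_len(pattern$rows - 1)])
  sizes <- diff(c(0, cut_at, length(vs)))
  if (any(sizes != pattern$cols))
    stop("ordering error: row grouping yields unequal rows (",
         paste(sizes, collapse = ", "), ")")
  row_of <- rep(seq_len(pattern$rows), times = sizes)
  idx <- integer(0)
  for (r in seq_len(pattern$rows)) {
    members <- ord[row_of == r]
    idx <- c(idx, members[order(u[members])])
  }
  out <- blobs[idx, , drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Project camera-frame points to pixel coordinates
#'
#' Homogeneous normalisation, radial/tangential distortion, then the
#' pixel mapping `x_px = fx * x_d + cx`, `y_px = fy * y_d + cy`.
#'
#' @param intrinsics a [camera_intrinsics()].
#' @param points_cam N x 3 matrix in the camera frame, metres (Z > 0).
#' @return N x 2 matrix of pixel coordinates.
#' @export
project_point <- function(intrinsics, points_cam) {
  points_cam <- as_points_matrix(points_cam)
  if (any(points_cam[, 3] <= 0))
    stop("behind-camera error: all points must have Z > 0")
  project_point_unchecked(intrinsics, points_cam)
}

# same projection without the Z guard; callers handle Z <= 0 themselves
project_point_unchecked <- function(intrinsics, points_cam) {
  x <- points_cam[, 1] / points_cam[, 3]
  y <- points_cam[, 2] / points_cam[, 3]
  r2 <- x^2 + y^2
  radial <- 1 + intrinsics$k1 * r2 + intrinsics$k2 * r2^2 +
    intrinsics$k3 * r2^3
  xd <- x * radial + 2 * intrinsics$p1 * x * y +
    intrinsics$p2 * (r2 + 2 * x^2)
  yd <- y * radial + intrinsics$p1 * (r2 + 2 * y^2) +
    2 * intrinsics$p2 * x * y
  cbind(x = intrinsics$fx * xd + intrinsics$cx,
        y = intrinsics$fy * yd + intrinsics$cy)
}

# undistort pixel coordinates to ideal normalized coordinates
# (fixed-point inversion of the distortion model)
undistort_pixels <- function(intrinsics, px, iterations = 20) {
  xd <- (px[, 1] - intrinsics$cx) / intrinsics$fx
  yd <- (px[, 2] - intrinsics$cy) / intrinsics$fy
  x <- xd; y <- yd
  for (i in seq_len(iterations)) {
    r2 <- x^2 + y^2
    radial <- 1 + intrinsics$k1 * r2 + intrinsics$k2 * r2^2 +
      intrinsics$k3 * r2^3
    dx <- 2 * intrinsics$p1 * x * y + intrinsics$p2 * (r2 + 2 * x^2)
    dy <- intrinsics$p1 * (r2 + 2 * y^2) + 2 * intrinsics$p2 * x * y
    x <- (xd - dx) / radial
    y <- (yd - dy) / radial
  }
  cbind(x, y)
}

# homography mapping plane coords (n x 2) to pixels (n x 2), normalized DLT
fit_homography <- function(obj, img) {
  norm_pts <- function(p) {
    mu <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, mu)^2))
    s <- sqrt(2) / mean(d)
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * mu[1], -s * mu[2], 1), 3, 3)
    list(T = T, p = cbind(s * (p[, 1] - mu[1]), s * (p[, 2] - mu[2])))
  }
  no <- norm_pts(obj); ni <- norm_pts(img)
  n <- nrow(obj)
  A <- matrix(0, 2 * n, 9)
  X <- no$p[, 1]; Y <- no$p[, 2]; u <- ni$p[, 1]; v <- ni$p[, 2]
  A[seq(1, 2 * n, 2), ] <- cbind(-X, -Y, -1, 0, 0, 0, u * X, u * Y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -X, -Y, -1, v * X, v * Y, v)
  h <- svd(A)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(ni$T) %*% H %*% no$T
  H / H[3, 3]
}

#' Calibrate thermal-camera intrinsics from board views
#'
#' Closed-form initialisation from per-view plane homographies followed by
#' Levenberg-Marquardt minimisation of the total reprojection error over
#' the camera matrix, the five distortion coefficients, and one rigid pose
#' per view (the planar bundle adjustment of the calibration problem).
#'
#' @param views list of `calibration_view` objects with status `"ok"`.
#' @param pattern a [pattern_spec()].
#' @return An object of class `intrinsic_calibration`: list with
#'   `intrinsics` ([camera_intrinsics()]), `poses` (per-view
#'   [rigid_transform()], board to camera), `rmse` (global reprojection
#'   RMSE, pixels), `per_view_rmse`, `converged`.
#' @export
calibrate_intrinsics <- function(views, pattern) {
  views <- Filter(function(v) identical(v$status, "ok"), views)
  n <- length(views)
  if (n < 3)
    stop("insufficient data: need at least 3 usable views, got ", n)
  grid <- pattern_grid(pattern)
  obj2 <- grid[, 1:2, drop = FALSE]
  feats <- lapply(views, function(v) {
    f <- as.matrix(v$features)
    if (nrow(f) != pattern$m) stop("view does not carry m features")
    f
  })
  Hs <- lapply(feats, function(f) fit_homography(obj2, f))

  # Zhang closed form: each homography gives two constraints on the image
  # of the absolute conic
  vfun <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vfun(H, 1, 2), vfun(H, 1, 1) - vfun(H, 2, 2))))
  sv <- svd(V)
  rel <- sv$d / sv$d[1]
  if (sum(rel < 1e-8) > 1 || rel[5] < 1e-8)
    stop("degenerate configuration: board orientations do not constrain ",
         "the camera (views too similar or coplanar-identical)")
  b <- sv$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]
  B33 <- b[6]
  den <- B11 * B22 - B12^2
  cy0 <- (B12 * B13 - B11 * B23) / den
  lam <- B33 - (B13^2 + cy0 * (B12 * B13 - B11 * B23)) / B11
  if (lam / B11 <= 0 || B11 * lam / den <= 0)
    stop("degenerate configuration: closed-form intrinsics are not ",
         "positive definite")
  fx0 <- sqrt(lam / B11)
  fy0 <- sqrt(lam * B11 / den)
  cx0 <- -B13 * fx0^2 / lam

  A0 <- matrix(c(fx0, 0, 0, 0, fy0, 0, cx0, cy0, 1), 3, 3)
  Ainv <- solve(A0)
  poses0 <- lapply(Hs, function(H) {
    h1 <- Ainv %*% H[, 1]; h2 <- Ainv %*% H[, 2]; h3 <- Ainv %*% H[, 3]
    lam <- 1 / sqrt(sum(h1^2))
    if (lam * h3[3] < 0) lam <- -lam # board in front of the camera
    r1 <- lam * h1; r2 <- lam * h2
    R <- nearest_rotation(cbind(r1, r2, cross3(r1, r2)))
    rigid_transform(R, lam * h3, check = FALSE)
  })

  obs <- do.call(rbind, feats)
  par0 <- c(fx0, fy0, cx0, cy0, 0, 0, 0, 0, 0,
            unlist(lapply(poses0, function(p)
              c(matrix_to_rodrigues(p$R), p$t))))
  residual <- function(par) {
    intr <- camera_intrinsics(max(par[1], 1e-6), max(par[2], 1e-6),
                              par[3], par[4], par[5], par[6], par[7],
                              par[8], par[9])
    res <- numeric(0)
    for (i in seq_len(n)) {
      base <- 9 + (i - 1) * 6
      R <- rodrigues_to_matrix(par[base + 1:3])
      t <- par[base + 4:6]
      cam <- sweep(grid %*% t(R), 2, t, "+")
      cam[, 3] <- pmax(cam[, 3], 1e-9)
      res <- c(res, project_point_unchecked(intr, cam) - feats[[i]])
    }
    res
  }
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par0, fn = residual,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 60, ftol = 1e-12, ptol = 1e-12)))
  par <- fit$par
  intr <- camera_intrinsics(par[1], par[2], par[3], par[4], par[5],
                            par[6], par[7], par[8], par[9])
  poses <- lapply(seq_len(n), function(i) {
    base <- 9 + (i - 1) * 6
    rigid_transform(rodrigues_to_matrix(par[base + 1:3]), par[base + 4:6],
                    check = FALSE)
  })
  res <- residual(par)
  m <- pattern$m
  per_view <- vapply(seq_len(n), function(i) {
    ri <- matrix(res, ncol = 2)[(i - 1) * m + seq_len(m), , drop = FALSE]
    sqrt(mean(rowSums(ri^2)))
  }, 0)
  rmse <- sqrt(sum(res^2) / (n * m))
  structure(list(intrinsics = intr, poses = poses, rmse = rmse,
                 per_view_rmse = per_view,
                 converged = fit$info %in% 1:4,
                 diagnostics = fit$message),
            class = "intrinsic_calibration")
}

#' @export
print.intrinsic_calibration <- function(x, ...) {
  cat(sprintf("Intrinsic calibration: %d views, reprojection RMSE %.4f px\n",
              length(x$poses), x$rmse))
  print(x$intrinsics)
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
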