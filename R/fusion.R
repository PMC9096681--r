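# Thermal fusion: assemble the moving line-scanner profiles into a 3D
# cloud, then assign each point the temperature of its nearest image
# pixel through the calibrated projection; points outside the camera's
# field of view receive the sentinel value and are never dropped.

#' Single LiDAR scan profile
#'
#' One planar sweep of the 2D line scanner: a uniform angular grid over a
#' 180 degree span (0.1667 degree resolution for the instrument modelled
#' here) with per-beam range and backscattered reflectance. `NA` range
#' marks a no-return beam.
#'
#' @param angles beam angles, radians, uniform grid.
#' @param ranges ranges, metres (`NA` = no return; finite values > 0).
#' @param reflectance per-beam reflectance, sensor units.
#' @param index profile index along the travel direction (0-based).
#' @return An object of class `scan_profile`.
#' @export
scan_profile <- function(angles, ranges, reflectance = NULL, index = 0) {
  stopifnot(length(angles) == length(ranges))
  if (length(angles) > 1) {
    steps <- diff(angles)
    if (max(abs(steps - steps[1])) > 1e-9)
      stop("angle grid is not uniform")
  }
  if (any(!is.na(ranges) & ranges <= 0))
    stop("ranges must be positive or NA (no return)")
  if (!is.null(reflectance)) stopifnot(length(reflectance) == length(ranges))
  structure(list(angles = angles, ranges = ranges,
                 reflectance = reflectance, index = index),
            class = "scan_profile")
}

#' Assemble scan profiles into a point cloud
#'
#' Converts each profile from polar to Cartesian in the scan plane
#' (`x = r cos(a)`, `z = r sin(a)`) and offsets profile `k` along the
#' travel axis `y` by `k * speed / scan_rate` (constant platform velocity
#' perpendicular to the scanning plane). No-return beams are skipped;
#' reflectance is carried per point.
#'
#' @param profiles list of [scan_profile()] objects sharing one angular
#'   grid.
#' @param speed platform speed, metres per second.
#' @param scan_rate scanning frequency, Hz.
#' @return A [point_cloud()] in the scanner frame.
#' @export
assemble_profiles <- function(profiles, speed = 0.020, scan_rate = 25) {
  stopifnot(length(profiles) >= 1, speed > 0, scan_rate > 0)
  a0 <- profiles[[1]]$angles
  for (p in profiles) {
    if (length(p$angles) != length(a0) || max(abs(p$angles - a0)) > 1e-9)
      stop("profiles do not share one angular grid")
  }
  step <- speed / scan_rate
  pts <- list(); refl <- list()
  has_refl <- !is.null(profiles[[1]]$reflectance)
  for (p in profiles) {
    ok <- !is.na(p$ranges)
    if (!any(ok)) next
    r <- p$ranges[ok]; a <- p$angles[ok]
    pts[[length(pts) + 1]] <- cbind(r * cos(a), p$index * step, r * sin(a))
    if (has_refl) refl[[length(refl) + 1]] <- p$reflectance[ok]
  }
  if (length(pts) == 0)
    return(point_cloud(matrix(numeric(0), 0, 3), frame_label = "scanner"))
  point_cloud(do.call(rbind, pts),
              reflectance = if (has_refl) unlist(refl),
              frame_label = "scanner")
}

#' Fusion configuration
#'
#' @param sentinel out-of-view temperature marker, degrees C; must lie
#'   outside the plausible scene range.
#' @param lookup pixel sampling rule; only `"nearest"` is provided
#'   (interpolation would blur blob/background boundaries).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(sentinel = -10, lookup = "nearest") {
  lookup <- match.arg(lookup, "nearest")
  structure(list(sentinel = sentinel, lookup = lookup),
            class = "fusion_config")
}

#' Fuse thermal-image temperatures into a point cloud
#'
#' Each point is mapped to the camera frame via the extrinsics and
#' projected through the full distortion model; when the projected pixel
#' lies inside the image (and the point is in front of the camera) the
#' nearest pixel's temperature is assigned, otherwise the sentinel. No
#' point is removed; the output cloud has exactly the input's size.
#'
#' By default no occlusion reasoning is applied: a point hidden behind
#' foliage samples the foreground pixel, exactly as a single-view
#' projection does. Setting `zbuffer = TRUE` enables a per-pixel depth
#' test that assigns the sentinel to points more than `zbuffer_tol`
#' metres behind the nearest point on their pixel.
#'
#' @param cloud a [point_cloud()].
#' @param image a [thermal_image()].
#' @param intrinsics a [camera_intrinsics()].
#' @param extrinsics [rigid_transform()] mapping cloud to camera frame.
#' @param cfg a [fusion_config()].
#' @param zbuffer enable the optional depth test (default off).
#' @param zbuffer_tol depth tolerance, metres.
#' @param buffer_cloud optional [point_cloud()] used to build the depth
#'   buffer (e.g. the merged two-side cloud, which also carries the
#'   occluders the fused side's own scan misses); defaults to `cloud`.
#' @return The cloud with its `temperature` attribute set.
#' @export
fuse_temperature <- function(cloud, image, intrinsics, extrinsics,
                             cfg = fusion_config(), zbuffer = FALSE,
                             zbuffer_tol = 0.05, buffer_cloud = NULL) {
  n <- n_points(cloud)
  out <- cloud
  if (n == 0) { out$temperature <- numeric(0); return(out) }
  cam <- transform_points(extrinsics, cloud$points)
  front <- cam[, 3] > 0
  temp <- rep(cfg$sentinel, n)
  if (any(front)) {
    px <- project_point_unchecked(intrinsics,
                                  cam[front, , drop = FALSE])
    val <- image_sample_nearest(image, px[, 1], px[, 2])
    if (zbuffer) {
      # depth buffer with a 3x3 splat: LiDAR points are sparse relative
      # to pixels, so an occluder is registered over its neighbourhood
      bcam <- if (is.null(buffer_cloud)) cam[front, , drop = FALSE]
        else {
          b <- transform_points(extrinsics, buffer_cloud$points)
          b[b[, 3] > 0, , drop = FALSE]
        }
      bpx <- project_point_unchecked(intrinsics, bcam)
      bx <- round_half_up(bpx[, 1]); by <- round_half_up(bpx[, 2])
      bz <- bcam[, 3]
      zmin <- rep(Inf, image$width * image$height)
      for (dx in -1:1) for (dy in -1:1) {
        jx <- bx + dx; jy <- by + dy
        okp <- jx >= 0 & jx < image$width & jy >= 0 & jy < image$height
        key <- jx[okp] + image$width * jy[okp] + 1L
        o <- order(bz[okp], decreasing = TRUE)
        zmin[key[o]] <- pmin(zmin[key[o]], bz[okp][o])
      }
      ix <- round_half_up(px[, 1]); iy <- round_half_up(px[, 2])
      z <- cam[front, 3]
      keyc <- ix + image$width * iy + 1L
      inb <- keyc >= 1 & keyc <= length(zmin)
      hidden <- inb & z > zmin[pmax(keyc, 1)] + zbuffer_tol
      val[hidden] <- NA
    }
    val[is.na(val)] <- cfg$sentinel
    temp[front] <- val
  }
  out$temperature <- temp
  out
}

#' Fuse a multi-frame thermal stream into a point cloud
#'
#' A moving rig captures many thermal frames per traverse; each point is
#' fused with the frame captured closest to it along the travel axis
#' (smallest viewing parallax), via [fuse_temperature()].
#'
#' @param cloud a [point_cloud()].
#' @param frames list of frames, each a list with `image`
#'   ([thermal_image()]), `extrinsics` ([rigid_transform()], cloud frame
#'   to that frame's camera) and `y` (frame position on the travel axis).
#' @param intrinsics a [camera_intrinsics()].
#' @param cfg a [fusion_config()].
#' @param ... further arguments passed to [fuse_temperature()]
#'   (e.g. `zbuffer`, `buffer_cloud`).
#' @return The cloud with its `temperature` attribute set.
#' @export
fuse_frames <- function(cloud, frames, intrinsics, cfg = fusion_config(),
                        ...) {
  stopifnot(length(frames) >= 1)
  ys <- vapply(frames, function(f) f$y, 0)
  grp <- apply(abs(outer(cloud$points[, 2], ys, "-")), 1, which.min)
  temp <- rep(cfg$sentinel, n_points(cloud))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- fuse_temperature(cloud_subset(cloud, idx), frames[[g]]$image,
                            intrinsics, frames[[g]]$extrinsics, cfg, ...)
    temp[idx] <- sub$temperature
  }
  out <- cloud
  out$temperature <- temp
  out
}

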