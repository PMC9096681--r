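#' Point cloud container
#'
#' 3D points in metres (sensor/rig frame) with optional per-point
#' backscattered reflectance (sensor units) and temperature (degrees C).
#' Out-of-view points carry the sentinel temperature rather than being
#' dropped; see [fuse_temperature()].
#'
#' @param points N x 3 numeric matrix of coordinates, metres.
#' @param reflectance optional length-N numeric vector.
#' @param temperature optional length-N numeric vector, degrees C.
#' @param frame_label free-text frame tag (e.g. "scanner", "east").
#' @param extra optional data.frame of length-N passthrough attributes
#'   (unknown PLY properties land here).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, reflectance = NULL, temperature = NULL,
                        frame_label = "", extra = NULL) {
  points <- as_points_matrix(points)
  n <- nrow(points)
  if (n > 0 && !all(is.finite(points)))
    stop("point coordinates must be finite")
  if (!is.null(reflectance)) {
    reflectance <- as.numeric(reflectance)
    if (length(reflectance) != n)
      stop("corrupt cloud: reflectance length ", length(reflectance),
           " does not match point count ", n)
  }
  if (!is.null(temperature)) {
    temperature <- as.numeric(temperature)
    if (length(temperature) != n)
      stop("corrupt cloud: temperature length ", length(temperature),
           " does not match point count ", n)
  }
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if (nrow(extra) != n)
      stop("corrupt cloud: extra attribute length mismatch")
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, reflectance = reflectance,
                 temperature = temperature, frame_label = frame_label,
                 extra = extra),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points%s\n", nrow(x$points),
              if (nzchar(x$frame_label)) paste0(" [", x$frame_label, "]")
              else ""))
  attrs <- c(if (!is.null(x$reflectance)) "reflectance",
             if (!is.null(x$temperature)) "temperature",
             names(x$extra))
  if (length(attrs)) cat("  attributes:", paste(attrs, collapse = ", "), "\n")
  if (nrow(x$points) > 0) {
    r <- apply(x$points, 2, range)
    cat(sprintf("  extent: x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Subset a point cloud by index
#'
#' Keeps all per-point attributes aligned.
#'
#' @param cloud a [point_cloud()].
#' @param idx integer or logical index vector.
#' @return The subset [point_cloud()].
#' @export
cloud_subset <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              reflectance = cloud$reflectance[idx],
              temperature = cloud$temperature[idx],
              frame_label = cloud$frame_label,
              extra = if (!is.null(cloud$extra))
                cloud$extra[idx, , drop = FALSE])
}

#' Concatenate point clouds
#'
#' Attributes present in only some inputs are padded with NA.
#'
#' @param ... [point_cloud()] objects.
#' @param frame_label label for the merged cloud.
#' @return The merged [point_cloud()].
#' @export
cloud_rbind <- function(..., frame_label = "") {
  clouds <- list(...)
  pts <- do.call(rbind, lapply(clouds, function(c) c$points))
  bind_attr <- function(field) {
    if (all(vapply(clouds, function(c) is.null(c[[field]]), TRUE)))
      return(NULL)
    unlist(lapply(clouds, function(c) {
      if (is.null(c[[field]])) rep(NA_real_, n_points(c)) else c[[field]]
    }))
  }
  point_cloud(pts, reflectance = bind_attr("reflectance"),
              temperature = bind_attr("temperature"),
              frame_label = frame_label)
}

#' Transform a point cloud rigidly
#'
#' @param cloud a [point_cloud()].
#' @param transform a [rigid_transform()].
#' @return The transformed cloud (attributes untouched).
#' @export
cloud_transform <- function(cloud, transform) {
  out <- cloud
  out$points <- transform_points(transform, cloud$points)
  colnames(out$points) <- c("x", "y", "z")
  out
}

#' Voxel-downsample a point cloud
#'
#' Points are binned on a cubic grid; each occupied voxel is replaced by
#' the centroid of its points (attribute means carried along).
#'
#' @param cloud a [point_cloud()].
#' @param voxel voxel edge length, metres.
#' @return The downsampled [point_cloud()].
#' @export
voxel_downsample <- function(cloud, voxel) {
  stopifnot(voxel > 0)
  if (n_points(cloud) == 0) return(cloud)
  key <- apply(floor(sweep(cloud$points, 2, c(0, 0, 0)) / voxel), 1, paste,
               collapse = "/")
  grp <- match(key, unique(key))
  agg <- function(v) if (is.null(v)) NULL else
    as.numeric(rowsum(v, grp) / tabulate(grp))
  pts <- rowsum(cloud$points, grp) / tabulate(grp)
  point_cloud(pts, reflectance = agg(cloud$reflectance),
              temperature = agg(cloud$temperature),
              frame_label = cloud$frame_label)
}
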