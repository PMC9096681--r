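# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is deterministic.

default_camera <- function() camera_intrinsics(570, 570, 320, 240, k1 = -0.1)

# random rigid transform with bounded rotation/translation
random_transform <- function(max_angle = pi / 4, max_t = 1) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -max_angle, max_angle)
  rigid_transform(thermocloud:::rodrigues_to_matrix(ax * ang),
                  runif(3, -max_t, max_t))
}

# 8-bit image with Gaussian bright spots at given (x, y) pixel centres
spot_image8 <- function(width, height, centers, sigma = 5, peak = 255) {
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), times = width), height, width)
  acc <- matrix(0, height, width)
  for (i in seq_len(nrow(centers)))
    acc <- pmax(acc, peak * exp(-((xs - centers[i, 1])^2 +
                                    (ys - centers[i, 2])^2) /
                                  (2 * sigma^2)))
  matrix(as.integer(round(acc)), height, width)
}

# points sampled on a sphere surface (uniform directions)
sphere_points <- function(n, centre = c(0, 0, 0), r = 1) {
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  sweep(v * r, 2, centre, "+")
}

# board poses spread over the scanning area, fully visible to both
# sensors (the valid-scan protocol of the extrinsic study)
board_pose_sample <- function() {
  rigid_transform(
    thermocloud:::rot_z(-pi / 2) %*% thermocloud:::rot_x(pi / 2) %*%
      (thermocloud:::rot_z(runif(1, -0.15, 0.15)) %*%
         thermocloud:::rot_y(runif(1, -0.2, 0.2)) %*%
         thermocloud:::rot_x(runif(1, -0.12, 0.12))),
    c(runif(1, 1.35, 1.8), 0.4 + runif(1, -0.07, 0.07),
      runif(1, 0.42, 0.52)))
}
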