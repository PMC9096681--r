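#' Rigid transform (rotation + translation)
#'
#' A rigid map `p -> R p + t` between 3D frames. Used for per-view board
#' poses, the pattern-to-scanner pose (initial, ICP correction, final), and
#' the LiDAR-to-camera extrinsics.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation, metres.
#' @param check validate the rotation (default TRUE).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), check = TRUE) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3)
  if (check) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      stop("R is not orthonormal")
    if (det(R) < 0)
      stop("R has negative determinant (reflection, not rotation)")
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  R:\n")
  print(round(x$R, 6))
  cat("  t: [", paste(sprintf("%.6f", x$t), collapse = ", "), "] m\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points N x 3 matrix of coordinates.
#' @return N x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  points <- as_points_matrix(points)
  sweep(points %*% t(transform$R), 2, transform$t, "+")
}

#' Compose rigid transforms
#'
#' `t_compose(A, B)` is the transform applying `B` first, then `A`
#' (matrix convention `A * B`).
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composed [rigid_transform()].
#' @export
t_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t, check = FALSE)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
t_inverse <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$t), check = FALSE)
}

#' Rotation angle between two transforms, degrees
#'
#' Geodesic distance on SO(3) between the rotation parts.
#'
#' @param a,b [rigid_transform()] objects.
#' @return Angle in degrees.
#' @export
rotation_angle_deg <- function(a, b = rigid_transform()) {
  Rrel <- t(b$R) %*% a$R
  cosang <- (sum(diag(Rrel)) - 1) / 2
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Rodrigues vector -> rotation matrix
rodrigues_to_matrix <- function(rvec) {
  theta <- sqrt(sum(rvec^2))
  if (theta < 1e-12) return(diag(3))
  k <- rvec / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# rotation matrix -> Rodrigues vector
matrix_to_rodrigues <- function(R) {
  cosang <- (sum(diag(R)) - 1) / 2
  theta <- acos(pmin(1, pmax(-1, cosang)))
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near pi: extract axis from R + I
    M <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(M), 0))
    # fix signs from off-diagonals
    i <- which.max(k)
    if (i == 1) k <- k * c(1, sign(M[1, 2]), sign(M[1, 3]))
    if (i == 2) k <- k * c(sign(M[1, 2]), 1, sign(M[2, 3]))
    if (i == 3) k <- k * c(sign(M[1, 3]), sign(M[2, 3]), 1)
    return(theta * k / sqrt(sum(k^2)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  theta * ax
}

# elementary rotations, angle in radians
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# project a near-rotation onto SO(3) (closest in Frobenius norm)
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

# best-fit rigid transform mapping A onto B (Kabsch/Umeyama, no scale)
fit_rigid <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  R <- nearest_rotation(t(H))
  rigid_transform(R, cb - as.numeric(R %*% ca), check = FALSE)
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be N x 3")
  storage.mode(points) <- "double"
  points
}
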