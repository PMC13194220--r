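#' Rigid 6-DOF pose
#'
#' A rotation given as three Euler angles in degrees about the fixed X, Y
#' and Z axes (applied in that order, i.e. `R = Rz %*% Ry %*% Rx`), plus a
#' translation.  The optional `center` is the point about which the
#' rotation acts: a point `v` maps to `R (v - center) + center +
#' translation`.  The fixed-axis XYZ convention maps directly onto the
#' per-axis +/-30 degree rotation bounds of the final alignment.
#'
#' @param rotation length-3 numeric, degrees about fixed X, Y, Z.
#' @param translation length-3 numeric, mm.
#' @param center length-3 numeric, rotation center (mm).
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                       center = c(0, 0, 0)) {
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("rigid_pose: rot (deg) [%.3f %.3f %.3f]  trans (mm) [%.3f %.3f %.3f]\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Euler angles (fixed-axis XYZ, degrees) to rotation matrix
#' @param rotation length-3 numeric, degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(rotation) {
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rotation matrix to Euler angles (fixed-axis XYZ, degrees)
#' @param R 3x3 rotation matrix.
#' @return Length-3 numeric, degrees.
#' @export
matrix_to_euler <- function(R) {
  sy <- -R[3, 1]
  if (abs(sy) < 1 - 1e-10) {
    ry <- asin(sy)
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: rz set to 0
    ry <- if (sy > 0) pi / 2 else -pi / 2
    rx <- atan2(-R[1, 2], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Homogeneous 4x4 matrix of a pose
#' @param pose a [rigid_pose()].
#' @return 4x4 transform matrix.
#' @export
pose_matrix <- function(pose) {
  R <- euler_to_matrix(pose$rotation)
  t <- pose$center + pose$translation - R %*% pose$center
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t
  M
}

#' Pose from a homogeneous matrix
#' @param M 4x4 rigid transform.
#' @param center rotation center for the returned representation.
#' @return A [rigid_pose()].
#' @export
pose_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  rot <- matrix_to_euler(R)
  # translation so that R (v - c) + c + t == R v + M[,4]
  t <- M[1:3, 4] - center + R %*% center
  rigid_pose(rot, drop(t), center)
}

#' Apply a pose to points or a mesh
#'
#' @param x a [tri_mesh()] or an `n x 3` point matrix / length-3 vector.
#' @param pose a [rigid_pose()].
#' @return Transformed object of the same kind.
#' @export
apply_pose <- function(x, pose) {
  R <- euler_to_matrix(pose$rotation)
  shift <- pose$center + pose$translation
  tp <- function(p) {
    p <- .as_points(p)
    sweep(sweep(p, 2, pose$center) %*% t(R), 2, shift, "+")
  }
  if (inherits(x, "tri_mesh")) tri_mesh(tp(x$vertices), x$faces)
  else if (inherits(x, "plane3")) plane3(drop(tp(x$point)),
                                         drop(R %*% x$normal))
  else if (inherits(x, "line3")) line3(drop(tp(x$point)),
                                       drop(R %*% x$direction))
  else {
    out <- tp(x)
    if (is.null(dim(x))) drop(out) else out
  }
}

#' Compose two poses
#'
#' Returns the pose equivalent to applying `first`, then `second`.
#'
#' @param first,second [rigid_pose()] objects.
#' @param center rotation center of the returned pose.
#' @return A [rigid_pose()].
#' @export
compose_poses <- function(first, second, center = c(0, 0, 0)) {
  pose_from_matrix(pose_matrix(second) %*% pose_matrix(first), center)
}

#' Invert a pose
#' @param pose a [rigid_pose()].
#' @param center rotation center of the returned pose.
#' @return The inverse [rigid_pose()].
#' @export
invert_pose <- function(pose, center = c(0, 0, 0)) {
  pose_from_matrix(solve(pose_matrix(pose)), center)
}
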