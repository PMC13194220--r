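# Frame standardization: put bone and plate into the canonical coordinate
# system (Z distal along the long axis, X volar, Y through the styloid
# side).  Right-side anatomy is mirrored onto the canonical left side at
# input and results can be mirrored back, so one pipeline serves both sides.

#' Principal axes of a point cloud
#'
#' Orthonormal axes ordered by decreasing variance (eigenvectors of the
#' vertex covariance).  Signs are fixed so that the skewness of the
#' projections onto each of the first two axes is non-negative; the third
#' axis completes a right-handed frame.  Downstream anatomical rules
#' (distal flip test, styloid Y, volar X) override these signs where the
#' anatomy dictates them.
#'
#' @param points `n x 3` numeric matrix.
#' @return 3x3 matrix whose columns are the axes (decreasing variance).
#' @export
principal_axes <- function(points) {
  points <- .as_points(points)
  if (nrow(unique(points)) < 2L) stop("degenerate point set for PCA")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  E <- ev$vectors
  for (k in 1:2) {
    pr <- x %*% E[, k]
    sk <- sum(pr^3)
    if (sk < 0) E[, k] <- -E[, k]
  }
  E[, 3] <- .cross3(E[, 1], E[, 2])
  E
}

.frame_result <- function(mesh, rotation, centroid, flipped, mirrored) {
  structure(list(mesh = mesh,
                 rotation = rotation,
                 centroid = centroid,
                 flipped = flipped,
                 mirrored = mirrored,
                 pose = pose_from_matrix(rbind(cbind(rotation,
                                                     -rotation %*% centroid),
                                               c(0, 0, 0, 1)))),
            class = "frame_result")
}

#' @export
print.frame_result <- function(x, ...) {
  cat("frame_result:",
      if (x$mirrored) "mirrored," else "",
      if (x$flipped) "flipped," else "",
      sprintf("origin shift [%.2f %.2f %.2f]\n",
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Map geometry into (or back out of) a standardized frame
#'
#' `apply_frame` maps input-frame geometry into the standardized frame
#' (including the left/right mirror, when one was recorded);
#' `unapply_frame` is its inverse.
#'
#' @param frame a `frame_result` from [standardize_bone()] or
#'   [standardize_plate()].
#' @param x a [tri_mesh()], [plane3()], [line3()], point matrix or
#'   length-3 vector.
#' @return The transformed object.
#' @export
apply_frame <- function(frame, x) {
  if (frame$mirrored) x <- .mirror_any(x)
  A <- frame$rotation
  ctr <- frame$centroid
  tp <- function(p) {
    p <- .as_points(p)
    sweep(p, 2, ctr) %*% t(A)
  }
  if (inherits(x, "tri_mesh")) tri_mesh(tp(x$vertices), x$faces)
  else if (inherits(x, "plane3")) plane3(drop(tp(x$point)), drop(A %*% x$normal))
  else if (inherits(x, "line3")) line3(drop(tp(x$point)), drop(A %*% x$direction))
  else { out <- tp(x); if (is.null(dim(x))) drop(out) else out }
}

#' @rdname apply_frame
#' @export
unapply_frame <- function(frame, x) {
  A <- frame$rotation
  ctr <- frame$centroid
  tp <- function(p) {
    p <- .as_points(p)
    sweep(p %*% A, 2, ctr, "+")
  }
  x <- if (inherits(x, "tri_mesh")) tri_mesh(tp(x$vertices), x$faces)
  else if (inherits(x, "plane3")) plane3(drop(tp(x$point)),
                                         drop(crossprod(A, x$normal)))
  else if (inherits(x, "line3")) line3(drop(tp(x$point)),
                                       drop(crossprod(A, x$direction)))
  else { out <- tp(x); if (is.null(dim(x))) drop(out) else out }
  if (frame$mirrored) x <- .mirror_any(x)
  x
}

.mirror_any <- function(x) {
  if (inherits(x, "tri_mesh")) return(mirror_mesh(x))
  if (inherits(x, "plane3")) {
    p <- x$point; p[1] <- -p[1]
    n <- x$normal; n[1] <- -n[1]
    return(plane3(p, n))
  }
  if (inherits(x, "line3")) {
    p <- x$point; p[1] <- -p[1]
    d <- x$direction; d[1] <- -d[1]
    return(line3(p, d))
  }
  if (is.null(dim(x))) { x[1] <- -x[1]; return(x) }
  x[, 1] <- -x[, 1]
  x
}

.rot_x180 <- diag(c(1, -1, -1))

.rot_z <- function(deg) {
  r <- deg * pi / 180
  rbind(c(cos(r), -sin(r), 0), c(sin(r), cos(r), 0), c(0, 0, 1))
}

#' Standardize the bone frame
#'
#' Origin at the bone mesh centroid, longest principal axis on Z.  The bone
#' is considered upright when the osteotomy planes lie above the centroid;
#' otherwise it is flipped in the Z direction (180 degrees about X) and
#' `flipped` is set.  +Y is the direction, orthogonal to Z, through the
#' most distal vertex (the styloid process); X completes the right-handed
#' frame and points towards the volar aspect.  Right-side bones are
#' mirrored onto the canonical left side first and the mirror is recorded.
#'
#' @param bone a [tri_mesh()].
#' @param osteotomy_planes list of two [plane3()] (the cut planes, in the
#'   same frame as `bone`).
#' @param side `"left"` or `"right"`.
#' @return A `frame_result` with elements `mesh`, `rotation`, `centroid`,
#'   `flipped`, `mirrored`, `pose`.
#' @export
standardize_bone <- function(bone, osteotomy_planes, side = c("left", "right")) {
  stopifnot(inherits(bone, "tri_mesh"))
  side <- match.arg(side)
  if (length(osteotomy_planes) != 2L ||
      !all(vapply(osteotomy_planes, inherits, logical(1), "plane3")))
    stop("osteotomy_planes must be a list of two plane3 objects")
  mirrored <- side == "right"
  if (mirrored) {
    bone <- mirror_mesh(bone)
    osteotomy_planes <- lapply(osteotomy_planes, .mirror_any)
  }
  ctr <- mesh_centroid(bone)
  E <- principal_axes(bone$vertices)
  # anchor the long axis to world +Z so the flip flag records whether the
  # *input* was upside down, not an intrinsic skewness sign
  if (E[3, 1] < 0) E[, 1] <- -E[, 1]
  A <- t(E[, c(3L, 2L, 1L)])  # rows: x (least var), y, z (most var)
  if (det(A) < 0) A[2, ] <- -A[2, ]
  plane_pts <- t(vapply(osteotomy_planes, function(p) p$point, numeric(3)))
  pz <- (sweep(plane_pts, 2, ctr) %*% t(A))[, 3]
  flipped <- mean(pz) <= 0
  if (flipped) A <- .rot_x180 %*% A
  v <- sweep(bone$vertices, 2, ctr) %*% t(A)
  i_top <- which.max(v[, 3])
  phi <- atan2(v[i_top, 2], v[i_top, 1]) * 180 / pi
  A <- .rot_z(90 - phi) %*% A
  mesh <- tri_mesh(sweep(bone$vertices, 2, ctr) %*% t(A), bone$faces)
  .frame_result(mesh, A, ctr, flipped, mirrored)
}

#' Standardize the plate frame
#'
#' Plate centroid at the origin, longest principal axis on Z.  The distal
#' head (the wide end carrying the two top corners) is put on +Z, decided
#' by comparing the lateral extent of the two ends; the contact (concave)
#' face is oriented towards -X so that it faces the bone's volar surface,
#' decided from the transverse curvature (the lateral edges of the plate
#' bend towards the bone).  A flat symmetric plate leaves the X sign at the
#' PCA skewness convention.
#'
#' @param plate a [tri_mesh()].
#' @return A `frame_result` (with `mirrored = FALSE`).
#' @export
standardize_plate <- function(plate) {
  stopifnot(inherits(plate, "tri_mesh"))
  ctr <- mesh_centroid(plate)
  E <- principal_axes(plate$vertices)
  A <- t(E[, c(3L, 2L, 1L)])
  if (det(A) < 0) A[2, ] <- -A[2, ]
  v <- sweep(plate$vertices, 2, ctr) %*% t(A)
  zr <- range(v[, 3])
  q <- 0.25 * (zr[2] - zr[1])
  top <- v[, 3] >= zr[2] - q
  bot <- v[, 3] <= zr[1] + q
  width <- function(sel) diff(range(v[sel, 2]))
  if (width(top) < width(bot)) {
    A <- .rot_x180 %*% A
    v <- sweep(plate$vertices, 2, ctr) %*% t(A)
  }
  ymax <- max(abs(v[, 2]))
  edge <- abs(v[, 2]) >= 0.8 * ymax
  bend <- mean(v[edge, 1]) - mean(v[, 1])
  if (bend > 1e-9) {
    A <- .rot_z(180) %*% A
    v <- sweep(plate$vertices, 2, ctr) %*% t(A)
  }
  mesh <- tri_mesh(v, plate$faces)
  .frame_result(mesh, A, ctr, flipped = FALSE, mirrored = FALSE)
}

#' Crop the distal bone segment
#'
#' Keeps exactly the faces whose three vertices all lie above `z_cut`
#' (strict policy: no sliver triangles at the cut).  The default of 40 mm
#' corresponds to roughly 17 percent of the average radius length and
#' keeps all clinically relevant plate positions while reducing mesh size.
#'
#' @param bone a standardized [tri_mesh()].
#' @param z_cut crop height in mm.
#' @return The distal sub-mesh as a [tri_mesh()].
#' @export
crop_distal <- function(bone, z_cut = 40) {
  stopifnot(inherits(bone, "tri_mesh"))
  above <- bone$vertices[, 3] > z_cut
  if (!any(above)) stop("empty crop: no vertex above z_cut = ", z_cut)
  keep_face <- above[bone$faces[, 1]] & above[bone$faces[, 2]] &
    above[bone$faces[, 3]]
  f <- bone$faces[keep_face, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  map <- integer(nrow(bone$vertices))
  map[used] <- seq_along(used)
  tri_mesh(bone$vertices[used, , drop = FALSE], matrix(map[f], ncol = 3L))
}
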