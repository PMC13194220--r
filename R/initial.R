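# Initial alignment: the deterministic five-step routine that produces the
# starting plate pose on the volar distal radius.

.ws_interp <- function(ws, y, what = c("z", "x")) {
  what <- match.arg(what)
  col <- if (what == "z") 3L else 1L
  ys <- ws[, 2]
  if (any(y < min(ys) - 1e-9) || any(y > max(ys) + 1e-9))
    stop("coverage error: plate corners extend beyond the watershed line")
  approx(ys, ws[, col], xout = .clamp(y, min(ys), max(ys)))$y
}

.rot_about_axis <- function(axis, deg) {
  u <- .unit(axis)
  th <- deg * pi / 180
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# accumulate: M <- rot about `axis` through `pivot`, then M
.compose_rot <- function(M, axis, pivot, deg) {
  R <- .rot_about_axis(axis, deg)
  S <- diag(4)
  S[1:3, 1:3] <- R
  S[1:3, 4] <- pivot - R %*% pivot
  S %*% M
}

.compose_trans <- function(M, t) {
  S <- diag(4)
  S[1:3, 4] <- t
  S %*% M
}

.mul_pt <- function(M, p) drop(M[1:3, 1:3] %*% p + M[1:3, 4])
.mul_pts <- function(M, P) sweep(P %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")

#' Compute the initial plate pose
#'
#' The five sub-steps, applied in order: (1) overlap the plate's alignment
#' line with the bone's initial alignment line (the plate centroid is
#' placed at the point of the bone line closest in Y to the watershed
#' center); (2) translate along Z until both top corners lie at least
#' `margin` mm below the watershed line (the binding corner exactly at the
#' margin); (3) rotate about the plate's center line (the alignment-line
#' direction through the plate centroid) until the bottom point contacts
#' the bone surface; (4) rotate about the plate's long axis to align the
#' top corners with the watershed X values; then, if the rotations
#' disturbed the margin, re-apply the Z translation; (5) translate along X
#' until the first plate vertex touches the bone surface.  Contact is
#' resolved by bisection on the signed surface distance.
#'
#' @param bone_lm a `bone_landmarks` object.
#' @param plate_lm a `plate_landmarks` object (standardized plate frame).
#' @param bone standardized bone [tri_mesh()].
#' @param plate standardized plate [tri_mesh()].
#' @param margin minimum watershed margin in mm.
#' @param contact_tol contact tolerance in mm.
#' @return Object of class `initial_placement`: `pose` (a [rigid_pose()]),
#'   `contact_vertex` (index of the first touching plate vertex),
#'   `watershed_margin` (mm).
#' @export
initial_place <- function(bone_lm, plate_lm, bone, plate, margin = 2,
                          contact_tol = 0.05) {
  stopifnot(inherits(bone_lm, "bone_landmarks"),
            inherits(plate_lm, "plate_landmarks"))
  ws <- bone_lm$watershed
  bl <- bone_lm$alignment_line
  M <- diag(4)

  # -- step 1: overlap alignment lines ------------------------------------
  u_p <- plate_lm$alignment_line$direction
  u_b <- bl$direction
  if (sum(u_p * u_b) < 0) u_b <- -u_b
  ax <- .cross3(u_p, u_b)
  if (.norm3(ax) > 1e-12) {
    ang <- atan2(.norm3(ax), sum(u_p * u_b)) * 180 / pi
    M <- .compose_rot(M, ax, plate_lm$centroid, ang)
  }
  ws_y_mid <- mean(range(ws[, 2]))
  if (abs(bl$direction[2]) < 1e-9)
    stop("degenerate alignment line: no Y component")
  s <- (ws_y_mid - bl$point[2]) / bl$direction[2]
  target <- bl$point + s * bl$direction
  M <- .compose_trans(M, target - .mul_pt(M, plate_lm$centroid))

  corners <- function() rbind(.mul_pt(M, plate_lm$top_left),
                              .mul_pt(M, plate_lm$top_right))
  margin_now <- function() {
    cc <- corners()
    min(.ws_interp(ws, cc[, 2], "z") - cc[, 3])
  }

  # -- step 2: Z translation to the watershed margin ----------------------
  M <- .compose_trans(M, c(0, 0, margin_now() - margin))

  # -- step 3: rotate about the center line until bottom contact ----------
  sd_bottom <- function(Mtry)
    signed_surface_distance(.mul_pt(Mtry, plate_lm$bottom), bone)
  center_axis <- drop(.mul_pt(M, plate_lm$centroid + u_p) -
                        .mul_pt(M, plate_lm$centroid))
  pivot <- .mul_pt(M, plate_lm$centroid)
  f3 <- function(a) sd_bottom(.compose_rot(M, center_axis, pivot, a))
  a_root <- .find_zero(f3, tol = 1e-3, max_angle = 90)
  if (is.null(a_root))
    stop("no-contact error: bottom point never reaches the bone within ±90°")
  M <- .compose_rot(M, center_axis, pivot, a_root)

  # -- step 4: rotate about the long axis to match watershed X ------------
  long_axis <- drop(.mul_pt(M, plate_lm$centroid + c(0, 0, 1)) -
                      .mul_pt(M, plate_lm$centroid))
  pivot <- .mul_pt(M, plate_lm$centroid)
  f4 <- function(a) {
    Mtry <- .compose_rot(M, long_axis, pivot, a)
    cc <- rbind(.mul_pt(Mtry, plate_lm$top_left),
                .mul_pt(Mtry, plate_lm$top_right))
    sum((cc[, 1] - .ws_interp(ws, cc[, 2], "x"))^2)
  }
  a4 <- optimize(f4, c(-45, 45), tol = 1e-4)$minimum
  M <- .compose_rot(M, long_axis, pivot, a4)

  # re-assert the margin if the rotations lowered a corner
  dz <- margin_now() - margin
  if (dz < -1e-9) M <- .compose_trans(M, c(0, 0, dz))

  # -- step 5: translate along X until first surface contact --------------
  f5 <- function(s) {
    vv <- .mul_pts(.compose_trans(M, c(s, 0, 0)), plate$vertices)
    min(signed_surface_distance(vv, bone))
  }
  s_root <- .approach_contact(f5, tol = contact_tol / 10)
  if (is.null(s_root))
    stop("no-contact error: plate never touches the bone along X")
  M <- .compose_trans(M, c(s_root, 0, 0))

  vv <- .mul_pts(M, plate$vertices)
  sd <- signed_surface_distance(vv, bone)
  structure(list(pose = pose_from_matrix(M),
                 contact_vertex = which.min(sd),
                 watershed_margin = margin_now(),
                 contact_distance = min(sd)),
            class = "initial_placement")
}

# Find the zero crossing of f nearest 0 by scanning both directions in 2deg
# steps, then bisecting.  Returns NULL if no sign change is found.
.find_zero <- function(f, tol = 1e-3, max_angle = 90, step = 2) {
  f0 <- f(0)
  if (abs(f0) <= tol) return(0)
  grid <- seq(step, max_angle, by = step)
  for (a in grid) {
    for (sg in c(-1, 1)) {
      fa <- f(sg * a)
      if (sign(fa) != sign(f0)) {
        lo <- sg * (a - step); hi <- sg * a
        flo <- f(lo)
        if (sign(flo) == sign(fa)) next
        for (i in 1:60) {
          mid <- (lo + hi) / 2
          fm <- f(mid)
          if (abs(fm) <= tol) return(mid)
          if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
        }
        return((lo + hi) / 2)
      }
    }
  }
  NULL
}

# First-contact translation along +X, approaching the bone from the volar
# side: find an offset with positive clearance, march inward (-X) until
# penetration, then bisect the last bracket.
.approach_contact <- function(f, tol = 5e-3, step = 1, max_out = 60) {
  hi <- 0
  fhi <- f(hi)
  while (fhi <= 0 && hi < max_out) {
    hi <- hi + 2 * step
    fhi <- f(hi)
  }
  if (fhi <= 0) return(NULL)
  lo <- hi - step
  flo <- f(lo)
  while (flo > 0 && lo > -max_out) {
    hi <- lo; fhi <- flo
    lo <- lo - step
    flo <- f(lo)
  }
  if (flo > 0) return(NULL)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) return(mid)
    if (fm <= 0) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  (lo + hi) / 2
}
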