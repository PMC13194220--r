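# Placement-comparison measures: unpaired maximum Hausdorff distance,
# total 3D rotation and total 3D translation between two plate placements.

#' Unpaired maximum Hausdorff distance between two meshes
#'
#' Symmetric worst-case nearest-neighbour distance between the two vertex
#' sets, without correspondence:
#' `max(max_i min_j |a_i - b_j|, max_j min_i |b_j - a_i|)`.
#'
#' @param a,b [tri_mesh()] objects (or point matrices).
#' @return Distance in mm.
#' @export
hausdorff_max <- function(a, b) {
  va <- if (inherits(a, "tri_mesh")) a$vertices else .as_points(a)
  vb <- if (inherits(b, "tri_mesh")) b$vertices else .as_points(b)
  if (nrow(va) == 0L || nrow(vb) == 0L) stop("empty mesh in hausdorff_max")
  max(max(cpp_nearest_dist(va, vb)), max(cpp_nearest_dist(vb, va)))
}

#' Rotation and translation difference between two poses
#'
#' The relative transform `r = b o a^-1` is decomposed into its geodesic
#' rotation angle (from the rotation-matrix trace, so independent of the
#' Euler representation) and the displacement of a reference point under
#' `r`.  "Total translation" is reference-point dependent under coupled
#' rotation; the plate centroid is the intended reference, defaulting to
#' the origin (the centroid of a standardized plate).
#'
#' @param a,b [rigid_pose()] objects.
#' @param point reference point (mm) whose displacement is reported.
#' @return Named numeric: `rotation_deg`, `translation_mm`.
#' @export
pose_difference <- function(a, b, point = c(0, 0, 0)) {
  Ma <- pose_matrix(a)
  Mb <- pose_matrix(b)
  R <- Mb %*% solve(Ma)
  tr <- sum(diag(R[1:3, 1:3]))
  ang <- acos(.clamp((tr - 1) / 2, -1, 1)) * 180 / pi
  p <- c(point, 1)
  disp <- (R %*% p)[1:3] - point
  c(rotation_deg = ang, translation_mm = .norm3(disp))
}

#' Compare two plate placements
#'
#' @param mesh_a,mesh_b placed plate meshes.
#' @param pose_a,pose_b optional [rigid_pose()] records of the placements;
#'   when supplied, rotation/translation differences are reported.
#' @param point reference point for the translation difference.
#' @return Object of class `comparison_metrics` with `hausdorff_mm` and,
#'   when poses are given, `rotation_deg` and `translation_mm`.
#' @export
compare_placements <- function(mesh_a, mesh_b, pose_a = NULL, pose_b = NULL,
                               point = c(0, 0, 0)) {
  out <- list(hausdorff_mm = hausdorff_max(mesh_a, mesh_b))
  if (!is.null(pose_a) && !is.null(pose_b)) {
    pd <- pose_difference(pose_a, pose_b, point = point)
    out$rotation_deg <- unname(pd["rotation_deg"])
    out$translation_mm <- unname(pd["translation_mm"])
  }
  structure(out, class = "comparison_metrics")
}

#' @export
print.comparison_metrics <- function(x, ...) {
  line <- sprintf("hausdorff %.3f mm", x$hausdorff_mm)
  if (!is.null(x$rotation_deg))
    line <- paste0(line, sprintf("  rotation %.3f deg  translation %.3f mm",
                                 x$rotation_deg, x$translation_mm))
  cat(line, "\n")
  invisible(x)
}
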