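# Landmark extraction: osteotomy planes, midplane, alignment line and
# watershed line on the bone; corner points and alignment line on the
# plate.

#' Detect the osteotomy planes from oversized triangles
#'
#' Segmented osteotomy models carry their planar cut faces tessellated with
#' conspicuously large triangles.  Faces with area at least
#' `area_factor` times the median face area are clustered by normal
#' direction (cosine >= `normal_cos` against the cluster seed, up to sign)
#' and plane offset (<= `offset_tol` mm); clusters with fewer than
#' `min_faces` members are discarded.  Exactly two clusters must remain;
#' each gets a least-squares plane fit.  The pair is ordered (distal,
#' proximal) by the Z of the fitted plane points, which is meaningful once
#' the bone is standardized; normals are oriented away from the mesh
#' centroid.
#'
#' Clusters must also be strongly oversized on average (mean face area at
#' least `strong_factor` times the median, matching the tessellation
#' signature of decimated planar cut faces) so that borderline-large
#' curved-surface patches cannot masquerade as cut faces.
#'
#' @param bone a [tri_mesh()].
#' @param area_factor multiple of the median face area above which a face
#'   counts as oversized.
#' @param normal_cos cosine threshold for grouping face normals.
#' @param offset_tol plane-offset tolerance in mm.
#' @param min_faces minimum faces per cluster.
#' @param strong_factor minimum mean cluster face area, as a multiple of
#'   the median face area.
#' @return List of two [plane3()]: `distal`, `proximal`.
#' @export
detect_osteotomy_planes <- function(bone, area_factor = 4, normal_cos = 0.99,
                                    offset_tol = 0.5, min_faces = 3L,
                                    strong_factor = 10) {
  stopifnot(inherits(bone, "tri_mesh"))
  areas <- triangle_areas(bone)
  big <- which(areas >= area_factor * stats::median(areas))
  if (length(big) < 2L * min_faces)
    stop("plane detection failed: found 0 cut-face clusters")
  v <- bone$vertices
  f <- bone$faces[big, , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / sqrt(rowSums(n^2))
  fc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  off <- rowSums(n * fc)
  cluster <- rep(0L, length(big))
  n_cl <- 0L
  seeds_n <- list(); seeds_o <- numeric(0)
  for (i in seq_along(big)) {
    assigned <- FALSE
    for (k in seq_len(n_cl)) {
      d <- sum(n[i, ] * seeds_n[[k]])
      o <- if (d >= 0) off[i] else -off[i]
      if (abs(d) >= normal_cos && abs(o - seeds_o[k]) <= offset_tol) {
        cluster[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      n_cl <- n_cl + 1L
      seeds_n[[n_cl]] <- n[i, ]
      seeds_o[n_cl] <- off[i]
      cluster[i] <- n_cl
    }
  }
  sizes <- tabulate(cluster, n_cl)
  med <- stats::median(areas)
  mean_area <- vapply(seq_len(n_cl), function(k)
    mean(areas[big][cluster == k]), numeric(1))
  good <- which(sizes >= min_faces & mean_area >= strong_factor * med)
  if (length(good) != 2L)
    stop("plane detection failed: found ", length(good),
         " cut-face clusters (expected 2)")
  ctr <- mesh_centroid(bone)
  fit <- lapply(good, function(k) {
    fk <- f[cluster == k, , drop = FALSE]
    pts <- v[unique(as.vector(fk)), , drop = FALSE]
    p0 <- colMeans(pts)
    ev <- eigen(crossprod(sweep(pts, 2, p0)), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    if (sum(nrm * (p0 - ctr)) < 0) nrm <- -nrm  # outward: away from centroid
    plane3(p0, nrm)
  })
  z <- vapply(fit, function(p) p$point[3], numeric(1))
  ord <- order(z, decreasing = TRUE)
  list(distal = fit[[ord[1]]], proximal = fit[[ord[2]]])
}

#' Midplane of the two osteotomy planes
#'
#' Point = midpoint of the two plane points; normal = normalized mean of
#' the sign-aligned normals.
#'
#' @param distal,proximal [plane3()] objects.
#' @return A [plane3()].
#' @export
compute_midplane <- function(distal, proximal) {
  n1 <- distal$normal
  n2 <- proximal$normal
  if (sum(n1 * n2) < 0) n2 <- -n2
  nm <- n1 + n2
  if (.norm3(nm) < 1e-9)
    stop("degenerate midplane: anti-parallel osteotomy normals")
  plane3((distal$point + proximal$point) / 2, nm)
}

#' Initial bone alignment line
#'
#' The most volar (maximum-X) vertex of the proximal segment defines a
#' plane parallel to the YZ plane; its intersection with the midplane is
#' the initial alignment line of the plate relative to the radius.
#'
#' @param bone standardized bone [tri_mesh()].
#' @param midplane a [plane3()].
#' @param z_cut crop height separating distal from proximal (mm).
#' @return List with `point_P` (length-3) and `line` ([line3()]).
#' @export
bone_alignment_line <- function(bone, midplane, z_cut = 40) {
  v <- bone$vertices
  prox <- v[, 3] <= z_cut
  if (!any(prox)) stop("proximal segment is empty below z_cut = ", z_cut)
  vp <- v[prox, , drop = FALSE]
  P <- vp[which.max(vp[, 1]), ]
  n <- midplane$normal
  nyz2 <- n[2]^2 + n[3]^2
  if (nyz2 < 1e-18)
    stop("no intersection: midplane is parallel to the YZ plane")
  dir <- .unit(.cross3(c(1, 0, 0), n))
  # least-norm point with x = P[1] on the midplane
  s <- (sum(n * midplane$point) - n[1] * P[1]) / nyz2
  q <- c(P[1], s * n[2], s * n[3])
  list(point_P = P, line = line3(q, dir))
}

#' Extract the watershed line of the distal radius
#'
#' For each 1 mm Y-slice of the distal segment the maximum-X vertex is
#' taken as a raw candidate; candidates whose Z deviates from the
#' candidates' mean Z by more than `z_band` are discarded (this captures
#' the volar rim and rejects slice maxima that come from the dorsally
#' tilted flare); the surviving candidates are smoothed by least-squares
#' polynomial regression of X and Z on Y and the smoothed polyline is
#' returned at the surviving slice centers.
#'
#' @param distal_segment cropped distal bone [tri_mesh()].
#' @param z_band Z-deviation tolerance in mm.
#' @param poly_degree polynomial degree of the smoothing fit.
#' @param slice_mm Y-slice width in mm.
#' @return List with `points` (k x 3 polyline, ordered by Y), `width`
#'   (Y-extent, mm), and `candidates` (raw per-slice maxima kept).
#' @export
compute_watershed <- function(distal_segment, z_band = 3, poly_degree = 3,
                              slice_mm = 1) {
  v <- distal_segment$vertices
  bins <- floor(v[, 2] / slice_mm)
  idx <- vapply(split(seq_len(nrow(v)), bins),
                function(i) i[which.max(v[i, 1])], integer(1))
  cand <- v[idx, , drop = FALSE]
  keep <- abs(cand[, 3] - mean(cand[, 3])) <= z_band
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) < poly_degree + 2L)
    stop("insufficient data: fewer than ", poly_degree + 2L,
         " watershed slices")
  cand <- cand[order(cand[, 2]), , drop = FALSE]
  y <- cand[, 2]
  fx <- lm(cand[, 1] ~ poly(y, poly_degree, raw = TRUE))
  fz <- lm(cand[, 3] ~ poly(y, poly_degree, raw = TRUE))
  yc <- slice_mm * (sort(unique(floor(y / slice_mm))) + 0.5)
  pts <- cbind(predict_poly(fx, yc), yc, predict_poly(fz, yc))
  list(points = pts, width = diff(range(yc)), candidates = cand)
}

predict_poly <- function(fit, y) {
  co <- coef(fit)
  co[is.na(co)] <- 0
  out <- rep(co[1], length(y))
  for (k in seq_len(length(co) - 1L)) out <- out + co[k + 1L] * y^k
  out
}

#' Y-extent of the bone at a given Z level
#'
#' Operational definition of the "radius width" used by the lateral
#' (X) movement constraint: the Y-extent of the bone vertices within
#' `half_band` mm of the midplane Z level.
#'
#' @param bone standardized bone [tri_mesh()].
#' @param z Z level (mm), typically the midplane point's Z.
#' @param half_band half-width of the measurement band (mm).
#' @return Width in mm.
#' @export
radius_width_at <- function(bone, z, half_band = 2) {
  v <- bone$vertices
  sel <- abs(v[, 3] - z) <= half_band
  if (!any(sel)) stop("no bone vertices near z = ", z)
  diff(range(v[sel, 2]))
}

#' Bundle all bone landmarks
#'
#' Runs the full landmark stage on a standardized bone: osteotomy planes
#' (transformed by the caller into the standardized frame), midplane,
#' alignment line, watershed line, widths and styloid vertex.
#'
#' @param bone standardized bone [tri_mesh()].
#' @param planes list of two [plane3()] in the standardized frame (order
#'   irrelevant; re-ordered by Z here).
#' @param z_cut crop height (mm).
#' @param z_band,poly_degree,slice_mm watershed parameters, see
#'   [compute_watershed()].
#' @return Object of class `bone_landmarks`.
#' @export
bone_landmarks <- function(bone, planes, z_cut = 40, z_band = 3,
                           poly_degree = 3, slice_mm = 1) {
  zs <- vapply(planes, function(p) p$point[3], numeric(1))
  distal <- planes[[which.max(zs)]]
  proximal <- planes[[which.min(zs)]]
  mid <- compute_midplane(distal, proximal)
  al <- bone_alignment_line(bone, mid, z_cut = z_cut)
  seg <- crop_distal(bone, z_cut = z_cut)
  ws <- compute_watershed(seg, z_band = z_band, poly_degree = poly_degree,
                          slice_mm = slice_mm)
  v <- bone$vertices
  structure(list(distal_plane = distal,
                 proximal_plane = proximal,
                 midplane = mid,
                 point_P = al$point_P,
                 alignment_line = al$line,
                 watershed = ws$points,
                 watershed_width = ws$width,
                 radius_width = radius_width_at(bone, mid$point[3]),
                 styloid = v[which.max(v[, 3]), ],
                 z_cut = z_cut),
            class = "bone_landmarks")
}

#' Plate landmarks: corners and alignment line
#'
#' The standardized plate is divided into four quadrants by the sign of
#' the coordinates along its first two principal axes (Z and Y after
#' standardization).  The vertex farthest from the centroid in each upper
#' quadrant is a top corner; the bottom corner is the vertex farthest from
#' the line joining the top corners; the alignment line runs through the
#' centroid parallel to the top-corner line.  Distance ties are broken by
#' lexicographically smallest (z, y, x) so the result does not depend on
#' STL vertex order.
#'
#' @param plate standardized plate [tri_mesh()].
#' @return Object of class `plate_landmarks` with fields `centroid`,
#'   `top_left`, `top_right`, `bottom`, `alignment_line`, `plate_length`.
#' @export
plate_landmarks <- function(plate) {
  stopifnot(inherits(plate, "tri_mesh"))
  v <- plate$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  pick_far <- function(sel, dist2) {
    if (!any(sel)) stop("landmark error: empty plate quadrant")
    i <- which(sel)
    d <- dist2[i]
    best <- d >= max(d) - 1e-9
    cand <- i[best]
    cand[order(v[cand, 3], v[cand, 2], v[cand, 1])][1]
  }
  d2 <- rowSums(vc^2)
  upper <- vc[, 3] > 0
  i_left <- pick_far(upper & vc[, 2] < 0, d2)
  i_right <- pick_far(upper & vc[, 2] >= 0, d2)
  top_left <- v[i_left, ]
  top_right <- v[i_right, ]
  dir <- top_right - top_left
  if (.norm3(dir) < 1e-9) stop("landmark error: coincident top corners")
  dir <- .unit(dir)
  rel <- sweep(v, 2, top_left)
  perp2 <- rowSums(rel^2) - (rel %*% dir)^2
  i_bot <- pick_far(rep(TRUE, nrow(v)), drop(perp2))
  z1 <- drop(v %*% c(0, 0, 1))
  structure(list(centroid = ctr,
                 top_left = top_left,
                 top_right = top_right,
                 bottom = v[i_bot, ],
                 alignment_line = line3(ctr, dir),
                 plate_length = diff(range(z1))),
            class = "plate_landmarks")
}
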