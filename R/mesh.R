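#' Indexed triangle mesh
#'
#' The universal geometry carrier of the package: an indexed triangle surface
#' in millimetres.  `vertices` is an `n x 3` numeric matrix, `faces` an
#' `m x 3` integer matrix of 1-based vertex indices.
#'
#' @param vertices numeric matrix with 3 columns (mm).
#' @param faces integer matrix with 3 columns, 1-based indices into
#'   `vertices`.
#' @return An object of class `tri_mesh`.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'               rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' mesh_centroid(m)
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  extent [mm]: x %.2f..%.2f, y %.2f..%.2f, z %.2f..%.2f\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Per-face triangle areas
#'
#' @param mesh a [tri_mesh()].
#' @return Numeric vector of face areas in mm^2.
#' @export
triangle_areas <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mesh centroid (unweighted vertex mean)
#'
#' The frame standardization only needs a robust interior reference point,
#' so the centroid is the plain arithmetic mean of the vertices.
#'
#' @param mesh a [tri_mesh()].
#' @return Length-3 numeric vector (mm).
#' @export
mesh_centroid <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  colMeans(mesh$vertices)
}

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must have 3 columns")
  points
}

#' Nearest-neighbour distances between point sets
#'
#' For each row of `points`, the Euclidean distance to the closest row of
#' `targets`.  This is the distance primitive of the placement objective
#' (plate vertices against bone vertices).
#'
#' @param points,targets numeric matrices with 3 columns (or length-3
#'   vectors).
#' @return Numeric vector, one distance (mm) per row of `points`.
#' @export
nearest_distances <- function(points, targets) {
  points <- .as_points(points)
  targets <- .as_points(targets)
  if (nrow(points) == 0L || nrow(targets) == 0L)
    stop("point sets must be non-empty")
  cpp_nearest_dist(points, targets)
}

#' Is a mesh watertight?
#'
#' TRUE when every undirected edge is shared by exactly two faces (each
#' connected component is closed).
#'
#' @param mesh a [tri_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Count points strictly inside a mesh
#'
#' Containment is decided by the generalized winding number with threshold
#' 0.5.  For non-watertight meshes the winding number is no longer a clean
#' indicator, so the test falls back to ray-crossing parity with a 3-ray
#' majority vote and emits a warning.
#'
#' @param points numeric matrix with 3 columns.
#' @param mesh a [tri_mesh()]; should be closed for a well-defined inside.
#' @return Non-negative integer count.
#' @export
count_points_inside <- function(points, mesh) {
  sum(points_inside(points, mesh))
}

#' Logical inside/outside classification of points against a mesh
#'
#' @inheritParams count_points_inside
#' @return Logical vector, one entry per point.
#' @export
points_inside <- function(points, mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  points <- .as_points(points)
  if (nrow(points) == 0L) return(logical(0))
  if (is_watertight(mesh)) {
    w <- cpp_winding_number(points, mesh$vertices, mesh$faces)
    w >= 0.5
  } else {
    warning("mesh is not watertight; using 3-ray parity majority vote",
            call. = FALSE)
    dirs <- rbind(c(1, 0.0317, 0.0173),
                  c(-0.0231, 1, 0.0409),
                  c(0.0127, -0.0371, 1))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    par <- cpp_ray_parity(points, mesh$vertices, mesh$faces, dirs)
    rowSums(par) >= 2L
  }
}

#' Unsigned and signed distances from points to a mesh surface
#'
#' `point_surface_distance` is the exact point-to-triangle minimum;
#' `signed_surface_distance` negates it for points inside the mesh.
#'
#' @inheritParams count_points_inside
#' @return Numeric vector of distances (mm); signed variant is negative
#'   inside the mesh.
#' @export
point_surface_distance <- function(points, mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  points <- .as_points(points)
  cpp_point_surface_dist(points, mesh$vertices, mesh$faces)
}

#' @rdname point_surface_distance
#' @export
signed_surface_distance <- function(points, mesh) {
  d <- point_surface_distance(points, mesh)
  inside <- points_inside(points, mesh)
  ifelse(inside, -d, d)
}

#' Weld duplicate vertices
#'
#' Merges vertices closer than `tol` (per coordinate, on a snapped grid) so
#' that faces share indices; drops degenerate (zero-area) faces.  STL stores
#' facets independently, so this is required before any index-based
#' landmarking.
#'
#' @param mesh a [tri_mesh()].
#' @param tol welding tolerance in mm.
#' @return A welded [tri_mesh()].
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  out_v <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3L)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  m <- tri_mesh(out_v, f)
  areas <- triangle_areas(m)
  tri_mesh(out_v, f[areas > 1e-12, , drop = FALSE])
}

#' Mirror a mesh across the YZ plane
#'
#' Negates X coordinates and reverses face winding so outward normals stay
#' outward.  Used to map right-side anatomy onto the canonical left side.
#'
#' @param mesh a [tri_mesh()].
#' @return The mirrored [tri_mesh()].
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  tri_mesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE])
}

#' Planes and lines
#'
#' Light containers for infinite planes and lines: a base point plus a unit
#' normal/direction.
#'
#' @param point length-3 numeric (mm).
#' @param normal,direction length-3 numeric; normalized internally.
#' @return An object of class `plane3` / `line3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = .unit(as.numeric(normal))),
            class = "plane3")
}

#' @rdname plane3
#' @export
line3 <- function(point, direction) {
  structure(list(point = as.numeric(point),
                 direction = .unit(as.numeric(direction))),
            class = "line3")
}

#' Signed distance of points to a plane
#' @param points points matrix or length-3 vector.
#' @param plane a [plane3()].
#' @return Numeric vector (mm), positive on the normal side.
#' @export
plane_distance <- function(points, plane) {
  points <- .as_points(points)
  drop((points - matrix(plane$point, nrow(points), 3, byrow = TRUE)) %*%
         plane$normal)
}
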