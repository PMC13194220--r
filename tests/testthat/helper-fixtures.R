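# Shared fixtures.  Expensive objects (synthetic cases, the standard
# placement) are built once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixtures)) assign(key, builder(), .fixtures)
  get(key, .fixtures)
}

# unit cube [0,1]^3 as 12 triangles (outward normals)
cube_mesh <- function(origin = c(0, 0, 0), size = 1) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))[, 3:1] * size
  v <- sweep(v, 2, origin, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  tri_mesh(v, f[, c(1L, 3L, 2L)])  # outward orientation
}

# thin horizontal slab (two z-sheets with side walls), for Hausdorff tests
slab_mesh <- function(nx = 6, ny = 6, thickness = 1) {
  xs <- seq(0, 10, length.out = nx)
  ys <- seq(0, 10, length.out = ny)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  v <- rbind(cbind(g, 0), cbind(g, thickness))
  idx <- function(i, j, top) (top * nx * ny) + (j - 1) * nx + i
  f <- NULL
  for (i in seq_len(nx - 1)) for (j in seq_len(ny - 1)) {
    f <- rbind(f,
               c(idx(i, j, 0), idx(i, j + 1, 0), idx(i + 1, j, 0)),
               c(idx(i + 1, j, 0), idx(i, j + 1, 0), idx(i + 1, j + 1, 0)),
               c(idx(i, j, 1), idx(i + 1, j, 1), idx(i, j + 1, 1)),
               c(idx(i + 1, j, 1), idx(i + 1, j + 1, 1), idx(i, j + 1, 1)))
  }
  tri_mesh(v, f)
}

random_rigid_pose <- function() {
  rigid_pose(runif(3, -180, 180), runif(3, -30, 30))
}

# standard synthetic case with landmarks (no optimization)
std_landmarked <- function() memo("std_landmarked", function() {
  b <- make_bone(bone_spec())
  p <- make_plate(plate_spec())
  planes <- detect_osteotomy_planes(b$mesh)
  fr <- standardize_bone(b$mesh, planes, side = "left")
  bl <- bone_landmarks(fr$mesh, lapply(planes, function(q) apply_frame(fr, q)))
  frp <- standardize_plate(p$mesh)
  lm <- plate_landmarks(frp$mesh)
  list(bone = b, plate = p, planes = planes, fr = fr, bone_lm = bl,
       fr_plate = frp, plate_lm = lm)
})

std_initial <- function() memo("std_initial", function() {
  s <- std_landmarked()
  initial_place(s$bone_lm, s$plate_lm, s$fr$mesh, s$fr_plate$mesh)
})

std_placement <- function() memo("std_placement", function() {
  s <- std_landmarked()
  optimize_pose(std_initial(), s$fr_plate$mesh, s$plate_lm, s$fr$mesh,
                s$bone_lm)
})

coarse_placement <- function(seed) memo(paste0("coarse_", seed), function() {
  cs <- synth_case(seed, resolution = "coarse")
  list(case = cs, result = place_plate(cs$bone$mesh, cs$plate$mesh))
})

expect_equal3 <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)
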