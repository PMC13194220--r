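test_that("triangle areas match closed forms and a brute-force oracle", {
  cube <- cube_mesh()
  expect_equal(triangle_areas(cube), rep(0.5, 12))
  tri <- tri_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(0, 0, 1)),
                  rbind(c(1, 2, 3)))
  expect_equal(triangle_areas(tri), 6)

  set.seed(11)
  v <- matrix(rnorm(300), ncol = 3)
  f <- t(replicate(100, sample(100, 3)))
  m <- tri_mesh(v, f)
  oracle <- vapply(seq_len(100), function(i) {
    a <- v[f[i, 2], ] - v[f[i, 1], ]
    b <- v[f[i, 3], ] - v[f[i, 1], ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    0.5 * sqrt(sum(cr^2))
  }, numeric(1))
  expect_lt(abs(sum(triangle_areas(m)) - sum(oracle)), 1e-9)
})

test_that("mesh centroid is the vertex mean and translation-equivariant", {
  cube <- cube_mesh()
  expect_equal(mesh_centroid(cube), c(0.5, 0.5, 0.5))
  t0 <- c(3, -2, 7)
  expect_equal(mesh_centroid(cube_mesh(origin = t0)), c(0.5, 0.5, 0.5) + t0)
  set.seed(2)
  v <- matrix(rnorm(60), ncol = 3)
  m <- tri_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(10, 11, 12)))
  expect_equal3(mesh_centroid(m), colMeans(v), 1e-12)
})

test_that("area and centroid are invariant under rigid motion", {
  set.seed(5)
  m <- cube_mesh()
  for (i in 1:5) {
    pose <- random_rigid_pose()
    m2 <- apply_pose(m, pose)
    expect_lt(abs(sum(triangle_areas(m2)) - 6) / 6, 1e-9)
    expect_equal3(mesh_centroid(m2), apply_pose(c(0.5, 0.5, 0.5), pose), 1e-9)
  }
})

test_that("nearest_distances equals the exhaustive oracle", {
  expect_equal(nearest_distances(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(7)
  a <- matrix(runif(600), ncol = 3)
  expect_equal(nearest_distances(a, a), rep(0, 200))
  b <- matrix(runif(900), ncol = 3)
  oracle <- apply(a, 1, function(p) sqrt(min(colSums((t(b) - p)^2))))
  expect_lt(max(abs(nearest_distances(a, b) - oracle)), 1e-9)
  expect_error(nearest_distances(a[0, , drop = FALSE], b), "non-empty")
})

test_that("containment matches the axis-aligned box oracle", {
  cube <- cube_mesh()
  expect_equal(count_points_inside(c(0.5, 0.5, 0.5), cube), 1L)
  expect_equal(count_points_inside(c(2, 2, 2), cube), 0L)
  set.seed(3)
  pts <- matrix(runif(1500, -1, 2), ncol = 3)
  oracle <- rowSums(pts > 0 & pts < 1) == 3L
  expect_identical(points_inside(pts, cube), oracle)
})

test_that("non-watertight meshes fall back to ray parity with a warning", {
  cube <- cube_mesh()
  open_cube <- tri_mesh(cube$vertices, cube$faces[-1, ])
  expect_false(is_watertight(open_cube))
  expect_warning(ins <- points_inside(rbind(c(0.5, 0.5, 0.5), c(2, 2, 2)),
                                      open_cube),
                 "not watertight")
  expect_identical(ins, c(TRUE, FALSE))
})

test_that("point-to-surface distances are exact and signed", {
  cube <- cube_mesh()
  pts <- rbind(c(0.5, 0.5, 2),     # above the top face
               c(0.5, 0.5, 0.75),  # inside
               c(2, 2, 2))         # nearest to the (1,1,1) corner
  d <- point_surface_distance(pts, cube)
  expect_equal(d, c(1, 0.25, sqrt(3)), tolerance = 1e-12)
  sd <- signed_surface_distance(pts, cube)
  expect_equal(sd, c(1, -0.25, sqrt(3)), tolerance = 1e-12)
})

test_that("vertex welding merges duplicates and drops degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0, 0, 1e-8), c(1, 0, 0), c(0, 1, 1))
  f <- rbind(c(1, 2, 3), c(4, 5, 6), c(1, 4, 2))  # last face degenerates
  m <- weld_vertices(tri_mesh(v, f), tol = 1e-6)
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$faces), 2)
})

test_that("planes and lines normalize their directions", {
  p <- plane3(c(0, 0, 5), c(0, 0, 10))
  expect_equal(sqrt(sum(p$normal^2)), 1, tolerance = 1e-12)
  expect_equal(plane_distance(rbind(c(1, 2, 8), c(0, 0, 0)), p), c(3, -5))
  l <- line3(c(1, 1, 1), c(2, 0, 0))
  expect_equal(l$direction, c(1, 0, 0))
  expect_error(plane3(c(0, 0, 0), c(0, 0, 0)), "zero")
})

test_that("mirroring negates X and preserves outward orientation", {
  cube <- cube_mesh()
  m <- mirror_mesh(cube)
  expect_equal(range(m$vertices[, 1]), c(-1, 0))
  expect_equal(count_points_inside(c(-0.5, 0.5, 0.5), m), 1L)
  expect_identical(mirror_mesh(m)$vertices, cube$vertices)
})
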