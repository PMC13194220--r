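test_that("osteotomy planes are recovered exactly from the cut faces", {
  s <- std_landmarked()
  det <- s$planes
  gt <- s$bone$truth$planes
  align <- function(n, ref) if (sum(n * ref) < 0) -n else n
  expect_lt(max(abs(align(det$distal$normal, gt$distal$normal) -
                      gt$distal$normal)), 1e-6)
  expect_lt(max(abs(align(det$proximal$normal, gt$proximal$normal) -
                      gt$proximal$normal)), 1e-6)
  # fitted points lie on the true planes
  expect_lt(abs(sum(gt$distal$normal * (det$distal$point - gt$distal$point))),
            1e-6)
  expect_gt(det$distal$point[3], det$proximal$point[3])
})

test_that("plane detection transforms covariantly under rigid motion", {
  s <- std_landmarked()
  pose <- rigid_pose(c(15, -40, 70), c(5, -3, 11))
  det2 <- detect_osteotomy_planes(apply_pose(s$bone$mesh, pose))
  ref <- apply_pose(s$planes$distal, pose)
  n2 <- det2$distal$normal
  if (sum(n2 * ref$normal) < 0) n2 <- -n2
  expect_lt(max(abs(n2 - ref$normal)), 1e-9)
  expect_lt(abs(sum(ref$normal * (det2$distal$point - ref$point))), 1e-9)
})

test_that("plane detection reports wrong cluster counts", {
  # uniform triangle sizes: no oversized faces at all
  expect_error(detect_osteotomy_planes(cube_mesh()), "0 cut-face clusters")
  # a third large coplanar fan on the bone -> three clusters
  s <- std_landmarked()
  bone <- s$bone$mesh
  n0 <- nrow(bone$vertices)
  ring <- cbind(9 * cos(seq(0, 2 * pi, length.out = 13)[-13]),
                9 * sin(seq(0, 2 * pi, length.out = 13)[-13]), -20)
  v2 <- rbind(bone$vertices, ring, c(0, 0, -20))
  fan <- cbind(n0 + 13L, n0 + seq_len(12), n0 + c(seq_len(11) + 1L, 1L))
  m3 <- tri_mesh(v2, rbind(bone$faces, fan))
  expect_error(detect_osteotomy_planes(m3), "3 cut-face clusters")
})

test_that("midplane averages points and sign-aligned normals", {
  p1 <- plane3(c(0, 0, 10), c(0, 0, 1))
  p2 <- plane3(c(0, 0, 20), c(0, 0, -1))  # anti-aligned representation
  mid <- compute_midplane(p1, p2)
  expect_equal(mid$point, c(0, 0, 15))
  expect_equal(abs(mid$normal), c(0, 0, 1))
  same <- compute_midplane(p1, p1)
  expect_equal(same$point, p1$point)
  expect_equal(same$normal, p1$normal)
  # 20 degrees apart: normal is the bisector
  n1 <- c(0, 0, 1)
  n2 <- c(sin(20 * pi / 180), 0, cos(20 * pi / 180))
  mid2 <- compute_midplane(plane3(c(0, 0, 0), n1), plane3(c(0, 0, 2), n2))
  bisector <- (n1 + n2) / sqrt(sum((n1 + n2)^2))
  expect_lt(max(abs(mid2$normal - bisector)), 1e-9)
})

test_that("the alignment line is the midplane / volar-plane intersection", {
  v <- rbind(c(7, 0, -50), c(0, 5, -45), c(-3, -4, -48), c(2, 1, 60))
  bone <- tri_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  flat <- bone_alignment_line(bone, plane3(c(0, 0, 0), c(0, 0, 1)), z_cut = 40)
  expect_equal(flat$point_P, c(7, 0, -50))
  expect_equal(flat$line$point, c(7, 0, 0))
  expect_equal(abs(flat$line$direction), c(0, 1, 0))

  n <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))  # tilted 10 deg about Y
  tl <- bone_alignment_line(bone, plane3(c(0, 0, 0), n), z_cut = 40)
  # closed form: x = 7 plane meets {q : n.q = 0}
  expect_lt(abs(sum(tl$line$point * n)), 1e-9)
  expect_equal(tl$line$point[1], 7)
  expect_lt(abs(sum(tl$line$direction * n)), 1e-9)
  expect_lt(abs(tl$line$direction[1]), 1e-9)

  expect_error(bone_alignment_line(bone, plane3(c(0, 0, 0), c(1, 0, 0))),
               "no intersection")
})

test_that("the watershed of an analytic ridge is recovered", {
  # half-cylinder of radius 10 with axis along Y: crest at x = 10, z = 0
  th <- seq(-pi / 2, pi / 2, length.out = 41)
  ys <- seq(-12, 12, length.out = 25)
  g <- expand.grid(th = th, y = ys)
  v <- cbind(10 * cos(g$th), g$y, 10 * sin(g$th))
  nth <- length(th)
  f <- NULL
  for (j in seq_len(length(ys) - 1)) for (i in seq_len(nth - 1)) {
    a <- (j - 1) * nth + i
    f <- rbind(f, c(a, a + 1, a + nth), c(a + 1, a + nth + 1, a + nth))
  }
  half_cyl <- tri_mesh(v, f)
  ws <- compute_watershed(half_cyl)
  expect_lt(max(abs(ws$points[, 1] - 10)), 1e-3)
  expect_lt(max(abs(ws$points[, 3] - 0)), 1e-3)

  # quadratic ridge with sigma = 0.05 noise: fit within 3 sigma everywhere
  set.seed(31)
  ridge_x <- function(y) 12 - 0.03 * y^2
  yg <- seq(-12, 12, by = 0.4)
  base <- cbind(ridge_x(yg) + rnorm(length(yg), sd = 0.05), yg, 0)
  back <- cbind(2, yg, rep_len(c(-6, 6), length(yg)))  # low-x filler
  vv <- rbind(base, back, back + c(0, 0, 0.5))
  nf <- nrow(vv)
  ff <- cbind(seq_len(nf - 2), seq_len(nf - 2) + 1L, seq_len(nf - 2) + 2L)
  ridge <- tri_mesh(vv, ff)
  ws2 <- compute_watershed(ridge)
  expect_lt(max(abs(ws2$points[, 1] - ridge_x(ws2$points[, 2]))), 0.15)

  # the 3-unit band drops Z outliers from the candidate set
  out <- rbind(base, c(12.5, 0.55, 10))   # would win its slice, far in Z
  vo <- rbind(out, back, back + c(0, 0, 0.5))
  no <- nrow(vo)
  ws3 <- compute_watershed(tri_mesh(vo, cbind(seq_len(no - 2),
                                              seq_len(no - 2) + 1L,
                                              seq_len(no - 2) + 2L)))
  expect_false(any(abs(ws3$candidates[, 3] - 10) < 1))
})

test_that("plate landmarks match the designed corners and symmetry", {
  s <- std_landmarked()
  lm <- s$plate_lm
  tr <- s$fr_plate
  expect_equal3(lm$top_left, apply_frame(tr, s$plate$truth$top_left), 1e-9)
  expect_equal3(lm$top_right, apply_frame(tr, s$plate$truth$top_right), 1e-9)
  expect_equal3(lm$bottom, apply_frame(tr, s$plate$truth$bottom), 1e-9)
  expect_equal(abs(lm$top_left[2]), abs(lm$top_right[2]), tolerance = 1e-6)
  expect_gt(min(lm$top_left[3], lm$top_right[3]), lm$bottom[3])
  # alignment line parallel to the top-corner line
  d <- lm$top_right - lm$top_left
  cosang <- sum(d * lm$alignment_line$direction) /
    sqrt(sum(d^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-9)
  expect_equal(lm$plate_length, s$plate$truth$plate_length, tolerance = 0.2)

  # detection is invariant to vertex-order permutation
  set.seed(17)
  perm <- sample(nrow(tr$mesh$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  shuf <- tri_mesh(tr$mesh$vertices[perm, ],
                   matrix(inv[tr$mesh$faces], ncol = 3))
  lm2 <- plate_landmarks(shuf)
  expect_equal3(lm2$top_left, lm$top_left, 1e-12)
  expect_equal3(lm2$bottom, lm$bottom, 1e-12)
})

test_that("radius width measures the Y extent at the midplane level", {
  s <- std_landmarked()
  w <- s$bone_lm$radius_width
  # direct oracle: Y extent of vertices within 2 mm of the midplane Z
  v <- s$fr$mesh$vertices
  sel <- abs(v[, 3] - s$bone_lm$midplane$point[3]) <= 2
  expect_equal(w, diff(range(v[sel, 2])))
  expect_gt(w, 20)
  expect_lt(w, 40)
})
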