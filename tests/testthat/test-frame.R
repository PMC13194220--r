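test_that("principal axes recover designed directions", {
  seg <- cbind(seq(0, 10, length.out = 50), 0, 0)
  E <- principal_axes(seg)
  expect_equal(abs(E[, 1]), c(1, 0, 0), tolerance = 1e-9)

  set.seed(6)
  u <- matrix(rnorm(6000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ell <- sweep(u, 2, c(30, 10, 5), "*")
  E <- principal_axes(ell)
  ang <- function(v, ref) acos(min(abs(sum(v * ref)), 1)) * 180 / pi
  expect_lt(ang(E[, 1], c(1, 0, 0)), 2)
  expect_lt(ang(E[, 2], c(0, 1, 0)), 2)
  expect_lt(ang(E[, 3], c(0, 0, 1)), 2)
  expect_equal(det(E), 1, tolerance = 1e-9)

  planar <- cbind(matrix(rnorm(200), ncol = 2), 0)
  expect_equal(abs(principal_axes(planar)[, 3]), c(0, 0, 1), tolerance = 1e-9)
  expect_error(principal_axes(rbind(c(1, 1, 1), c(1, 1, 1))), "degenerate")
})

test_that("bone standardization is anatomically oriented and idempotent", {
  s <- std_landmarked()
  mesh <- s$fr$mesh
  v <- mesh$vertices
  i_top <- which.max(v[, 3])
  expect_gte(v[i_top, 2], 0)                 # styloid in the +Y half-space
  expect_equal3(mesh_centroid(mesh), c(0, 0, 0), 1e-9)
  expect_lt(abs(v[i_top, 1]), 1e-6)          # styloid on the x = 0 plane

  planes_std <- lapply(s$planes, function(p) apply_frame(s$fr, p))
  fr2 <- standardize_bone(mesh, planes_std, side = "left")
  expect_lt(max(abs(fr2$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(fr2$centroid)), 1e-9)
})

test_that("bone standardization is rigid-motion equivariant", {
  s <- std_landmarked()
  set.seed(12)
  for (i in 1:5) {
    pose <- random_rigid_pose()
    bone2 <- apply_pose(s$bone$mesh, pose)
    planes2 <- lapply(s$planes, function(p) apply_pose(p, pose))
    fr2 <- standardize_bone(bone2, planes2, side = "left")
    expect_lt(max(abs(fr2$mesh$vertices - s$fr$mesh$vertices)), 1e-6)
  }
})

test_that("an upside-down bone is flipped back to the same frame", {
  s <- std_landmarked()
  flip <- rigid_pose(c(180, 0, 0))
  bone2 <- apply_pose(s$bone$mesh, flip)
  planes2 <- lapply(s$planes, function(p) apply_pose(p, flip))
  fr2 <- standardize_bone(bone2, planes2, side = "left")
  expect_lt(max(abs(fr2$mesh$vertices - s$fr$mesh$vertices)), 1e-6)
  expect_false(identical(fr2$flipped, s$fr$flipped))
})

test_that("a mirrored bone with the opposite side label gives the same frame", {
  s <- std_landmarked()
  bone_r <- mirror_mesh(s$bone$mesh)
  planes_r <- lapply(s$planes, function(p) {
    q <- p; q$point[1] <- -q$point[1]; q$normal[1] <- -q$normal[1]; q
  })
  fr_r <- standardize_bone(bone_r, planes_r, side = "right")
  expect_true(fr_r$mirrored)
  expect_identical(fr_r$mesh$vertices, s$fr$mesh$vertices)
  # unapply_frame returns to the mirrored input exactly
  back <- unapply_frame(fr_r, fr_r$mesh)
  expect_lt(max(abs(back$vertices - bone_r$vertices)), 1e-9)
})

test_that("plate standardization puts the head up, contact face volar", {
  s <- std_landmarked()
  mesh <- s$fr_plate$mesh
  v <- mesh$vertices
  zr <- range(v[, 3])
  q <- 0.25 * diff(zr)
  w_top <- diff(range(v[v[, 3] >= zr[2] - q, 2]))
  w_bot <- diff(range(v[v[, 3] <= zr[1] + q, 2]))
  expect_gt(w_top, w_bot)                       # T-head distal
  edge <- abs(v[, 2]) >= 0.8 * max(abs(v[, 2]))
  expect_lt(mean(v[edge, 1]), mean(v[, 1]))     # edges bend towards -X
  expect_equal3(mesh_centroid(mesh), c(0, 0, 0), 1e-9)

  set.seed(13)
  for (i in 1:3) {
    fr2 <- standardize_plate(apply_pose(s$plate$mesh, random_rigid_pose()))
    expect_lt(max(abs(fr2$mesh$vertices - mesh$vertices)), 1e-6)
  }
})

test_that("distal crop keeps exactly the faces above the threshold", {
  s <- std_landmarked()
  seg <- crop_distal(s$fr$mesh, 40)
  expect_true(all(seg$vertices[, 3] > 40))
  expect_lt(nrow(seg$vertices), nrow(s$fr$mesh$vertices))
  all_kept <- crop_distal(s$fr$mesh, min(s$fr$mesh$vertices[, 3]) - 1)
  expect_equal(nrow(all_kept$vertices), nrow(s$fr$mesh$vertices))
  expect_equal(nrow(all_kept$faces), nrow(s$fr$mesh$faces))
  expect_error(crop_distal(s$fr$mesh, 1e4), "empty crop")
})
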