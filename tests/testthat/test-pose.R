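test_that("Euler angles and rotation matrices round-trip", {
  set.seed(4)
  for (i in 1:20) {
    rot <- runif(3, -170, 170)
    rot[2] <- runif(1, -85, 85)  # stay clear of gimbal lock
    R <- euler_to_matrix(rot)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    R2 <- euler_to_matrix(matrix_to_euler(R))
    expect_lt(max(abs(R - R2)), 1e-9)
  }
})

test_that("pose application, composition and inversion are consistent", {
  set.seed(9)
  pts <- matrix(rnorm(30), ncol = 3)
  a <- random_rigid_pose()
  b <- random_rigid_pose()
  via_mat <- function(M, p) t(M[1:3, 1:3] %*% t(p) + M[1:3, 4])
  expect_equal3(apply_pose(pts, a), via_mat(pose_matrix(a), pts), 1e-10)
  ab <- compose_poses(a, b)
  expect_equal3(apply_pose(pts, ab), apply_pose(apply_pose(pts, a), b), 1e-9)
  inv <- invert_pose(a)
  expect_equal3(apply_pose(apply_pose(pts, a), inv), pts, 1e-9)
  # rotation about a center: the center is a fixed point
  c0 <- c(1, 2, 3)
  pc <- rigid_pose(c(10, 20, 30), c(0, 0, 0), center = c0)
  expect_equal3(apply_pose(c0, pc), c0, 1e-12)
})

test_that("pose differences match trace/quaternion oracles", {
  a <- rigid_pose(c(12, -5, 40), c(1, 2, 3))
  expect_equal(unname(pose_difference(a, a)), c(0, 0))
  expect_equal(unname(pose_difference(rigid_pose(), rigid_pose(
    translation = c(3, 4, 0)))), c(0, 5))

  # composition 20 deg about X then 20 deg about Z: quaternion oracle
  quat <- function(axis, deg) {
    th <- deg * pi / 360
    c(cos(th), sin(th) * axis)
  }
  qmul <- function(p, q) {
    c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
      p[1] * q[2:4] + q[1] * p[2:4] +
        c(p[3] * q[4] - p[4] * q[3],
          p[4] * q[2] - p[2] * q[4],
          p[2] * q[3] - p[3] * q[2]))
  }
  q <- qmul(quat(c(0, 0, 1), 20), quat(c(1, 0, 0), 20))
  oracle_deg <- 2 * acos(abs(q[1])) * 180 / pi
  got <- pose_difference(rigid_pose(), rigid_pose(c(20, 0, 20)))
  expect_equal(unname(got["rotation_deg"]), oracle_deg, tolerance = 1e-9)

  # Euler representation ambiguity: (180,180,180) is the identity rotation
  expect_equal(unname(pose_difference(rigid_pose(c(180, 180, 180)),
                                      rigid_pose())["rotation_deg"]),
               0, tolerance = 1e-9)
})

test_that("rotation angles satisfy the triangle inequality", {
  set.seed(21)
  for (i in 1:20) {
    a <- random_rigid_pose(); b <- random_rigid_pose(); c <- random_rigid_pose()
    ab <- pose_difference(a, b)["rotation_deg"]
    bc <- pose_difference(b, c)["rotation_deg"]
    ac <- pose_difference(a, c)["rotation_deg"]
    expect_lte(ac, ab + bc + 1e-9)
  }
})
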