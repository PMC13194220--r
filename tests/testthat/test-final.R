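test_that("the objective is the stated linear combination of its terms", {
  zero <- list(d_plate = 0, d_top = 0, d_bottom = 0, M_penalty = 0,
               theta_penalty = 0, y_dev = 0)
  expect_equal(objective_value(zero), 0)
  one <- modifyList(zero, list(d_plate = 1))
  expect_equal(objective_value(one, objective_weights(1, 2, 3, 4, 5)), 1)
  top2 <- modifyList(zero, list(d_top = 2))
  expect_equal(objective_value(top2), 210)

  set.seed(41)
  for (i in 1:25) {
    t <- list(d_plate = runif(1, 0, 100), d_top = runif(1, 0, 10),
              d_bottom = runif(1, 0, 10), M_penalty = sample(0:50, 1),
              theta_penalty = runif(1, 0, 90), y_dev = runif(1, 0, 5))
    w <- objective_weights(runif(1, 0, 200), runif(1, 0, 200),
                           runif(1, 0, 10), runif(1, 0, 10), runif(1, 0, 100))
    by_hand <- t$d_plate + w$a * t$d_top + w$b * t$d_bottom +
      w$c * t$M_penalty + w$d * t$theta_penalty + w$e * t$y_dev
    expect_equal(objective_value(t, w), by_hand, tolerance = 1e-12)
  }
  expect_error(objective_weights(a = -1), "non-negative")
})

test_that("objective terms behave on degenerate geometries", {
  s <- std_landmarked()
  cube <- cube_mesh()
  cube_lm <- plate_landmarks(cube)
  # mesh against an exact copy of itself: zero distance, nothing inside
  terms <- compute_objective_terms(rigid_pose(), cube, cube_lm, cube, NULL)
  expect_equal(terms$d_plate, 0)
  expect_equal(terms$M_penalty, 0L)
  # plate fully inside a big enclosing box: all vertices counted
  box <- cube_mesh(origin = c(-10, -10, -10), size = 20)
  terms2 <- compute_objective_terms(rigid_pose(), cube, cube_lm, box, NULL)
  expect_equal(terms2$M_penalty, nrow(cube$vertices))
  # point-to-vertex distance to a flat slab grid: closed-form check
  slab <- slab_mesh()
  p <- tri_mesh(rbind(c(2, 2, 6), c(2, 4, 6), c(4, 2, 5), c(4, 4, 4)),
                rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  plm <- plate_landmarks(p)
  t3 <- suppressWarnings(  # the open slab exercises the ray-parity fallback
    compute_objective_terms(rigid_pose(), p, plm, slab, NULL))
  oracle <- min(sqrt(colSums((t(slab$vertices) - apply_pose(plm$bottom,
                                                            rigid_pose()))^2)))
  expect_equal(t3$d_bottom, oracle, tolerance = 1e-9)
})

test_that("distance and count terms are invariant under common rigid motion", {
  s <- std_landmarked()
  init <- std_initial()
  plate_i <- apply_pose(s$fr_plate$mesh, init$pose)
  lm_i <- transform_plate_landmarks(s$plate_lm, init$pose)
  t0 <- compute_objective_terms(rigid_pose(), plate_i, lm_i, s$fr$mesh,
                                s$bone_lm)
  set.seed(51)
  pose <- random_rigid_pose()
  t1 <- compute_objective_terms(rigid_pose(), apply_pose(plate_i, pose),
                                transform_plate_landmarks(lm_i, pose),
                                apply_pose(s$fr$mesh, pose), s$bone_lm)
  expect_equal(t1$d_plate, t0$d_plate, tolerance = 1e-9)
  expect_equal(t1$d_top, t0$d_top, tolerance = 1e-9)
  expect_equal(t1$d_bottom, t0$d_bottom, tolerance = 1e-9)
  expect_identical(t1$M_penalty, t0$M_penalty)
  expect_equal(t1$theta_penalty, t0$theta_penalty, tolerance = 1e-6)
  # y_dev is a world-Y quantity: invariant under translation only
  tr <- rigid_pose(translation = c(4, -7, 9))
  t2 <- compute_objective_terms(rigid_pose(), apply_pose(plate_i, tr),
                                transform_plate_landmarks(lm_i, tr),
                                apply_pose(s$fr$mesh, tr), s$bone_lm)
  expect_equal(t2$y_dev, t0$y_dev, tolerance = 1e-9)
})

test_that("pose bounds reproduce the prescribed intervals", {
  ws <- cbind(seq(9, 11, length.out = 21), seq(-10, 10), 50)
  fake_bl <- structure(list(radius_width = 20, watershed_width = 20,
                            watershed = ws), class = "bone_landmarks")
  fake_pl <- structure(list(plate_length = 50), class = "plate_landmarks")
  bone <- cube_mesh(origin = c(0, 0, 69))  # max Z = 70
  init <- c(10, 0, 20)
  b <- build_bounds(init, fake_bl, fake_pl, bone)
  expect_equal(b$trans_lower[1], 10 - 5)      # quarter of the radius width
  expect_equal(b$trans_upper[1], 10 + 5)
  expect_equal(b$trans_lower[2], -10)         # watershed width, re-centered
  expect_equal(b$trans_upper[2], 10)
  # vertical: bottom edge within 1.5 plate lengths of the bone top
  expect_equal(b$trans_lower[3] - 50 / 2, 70 - 1.5 * 50)
  expect_equal(b$trans_upper[3], init[3])     # cannot rise above initial
  expect_equal(b$rot_lower, rep(-30, 3))
  # a plate too short to reach down from the bone top inverts the interval
  short_pl <- structure(list(plate_length = 5), class = "plate_landmarks")
  expect_error(build_bounds(init, fake_bl, short_pl, bone), "bounds error")
})

test_that("optimization improves the objective and respects the bounds", {
  for (seed in 1:2) {
    cp <- coarse_placement(seed)
    res <- cp$result$final
    expect_lte(res$objective_value, res$initial_objective + 1e-9)
    lo <- c(res$bounds$rot_lower, res$bounds$trans_lower)
    hi <- c(res$bounds$rot_upper, res$bounds$trans_upper)
    expect_true(all(res$par >= lo - 1e-9))
    expect_true(all(res$par <= hi + 1e-9))
    expect_equal(objective_value(res$terms, objective_weights()),
                 res$objective_value, tolerance = 1e-9)
  }
})

test_that("the standard case keeps margin and penetration under control", {
  s <- std_landmarked()
  res <- std_placement()
  t <- res$terms
  expect_true(t$M_penalty == 0L ||
                t$M_penalty <= res$initial_terms$M_penalty)
  # the Z bound caps the top edge at its initial (margin-binding) height;
  # allowed rotations may trade a fraction of the margin, but the corners
  # must never rise past the watershed line itself
  lmf <- transform_plate_landmarks(s$plate_lm, res$pose)
  ws <- s$bone_lm$watershed
  wz <- approx(ws[, 2], ws[, 3], xout = c(lmf$top_left[2], lmf$top_right[2]))$y
  margins <- wz - c(lmf$top_left[3], lmf$top_right[3])
  expect_gte(min(margins), 0)
  placed <- apply_pose(s$fr_plate$mesh, res$pose)
  init_top <- max(apply_pose(s$fr_plate$mesh, std_initial()$pose)$vertices[, 3])
  expect_lte(max(placed$vertices[, 3]), init_top + 0.5)
})

test_that("degenerate weights and restarts do not break the optimizer", {
  s <- std_landmarked()
  init <- std_initial()
  res0 <- optimize_pose(init, s$fr_plate$mesh, s$plate_lm, s$fr$mesh,
                        s$bone_lm, weights = objective_weights(0, 0, 0, 0, 0),
                        max_iter = 30)
  expect_lte(res0$objective_value, res0$initial_objective + 1e-9)
  # restarting at a converged solution stays put
  res <- std_placement()
  res2 <- optimize_pose(init, s$fr_plate$mesh, s$plate_lm, s$fr$mesh,
                        s$bone_lm, start = res$par, max_iter = 100)
  expect_lte(res2$objective_value, res$objective_value * 1.01 + 1e-9)
})
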