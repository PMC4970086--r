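# Quaternion algebra, joint motion, RMSD and quality labels.

test_that("quaternion product matches identity and inverse cases", {
  id <- c(1, 0, 0, 0)
  q <- quat_from_axis_angle(c(0, 1, 0), 37)
  expect_equal(quat_multiply(id, q), q, tolerance = 1e-12)
  expect_equal(quat_multiply(q, id), q, tolerance = 1e-12)
  expect_equal(quat_multiply(q, quat_conjugate(q)), id, tolerance = 1e-12)
  expect_error(quat_multiply(c(0, 0, 0, 0), q), "zero norm")
})

test_that("quaternion composition agrees with the rotation-matrix oracle", {
  set.seed(11)
  qa <- random_quats(1000)
  qb <- random_quats(1000)
  prod <- quat_multiply(qa, qb)
  worst <- 0
  for (i in seq_len(nrow(qa))) {
    oracle <- quat_to_rotmat(qa[i, ]) %*% quat_to_rotmat(qb[i, ])
    worst <- max(worst, max(abs(quat_to_rotmat(prod[i, ]) - oracle)))
  }
  expect_lt(worst, 1e-9)
})

test_that("relative orientation reproduces the distal stream", {
  set.seed(21)
  n <- 50
  time <- (seq_len(n) - 1) / 60
  prox <- quat_series(time, random_quats(n))
  dist <- quat_series(time, random_quats(n))
  rel <- relative_orientation_series(prox, dist)
  rebuilt <- quat_multiply(prox$q, rel$q)
  expect_lt(quat_maxdiff(rebuilt, dist$q), 1e-9)

  same <- relative_orientation_series(prox, prox)
  expect_lt(quat_maxdiff(same$q, matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE)), 1e-9)

  rot30 <- quat_series(time, matrix(quat_from_axis_angle(c(0, 0, 1), 30), n, 4, byrow = TRUE))
  idser <- quat_series(time, matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE))
  expect_equal(global_motion_angle(relative_orientation_series(idser, rot30))$angle[2],
               30, tolerance = 1e-9)

  shifted <- quat_series(time + 0.5, dist$q)
  expect_error(relative_orientation_series(prox, shifted), "alignment")
})

test_that("referencing to the initial sample yields identity start and is invertible", {
  set.seed(22)
  n <- 40
  time <- (seq_len(n) - 1) / 60
  rel <- quat_series(time, random_quats(n))
  rel0 <- express_relative_to_initial(rel)
  expect_lt(quat_maxdiff(rel0$q[1, , drop = FALSE],
                         matrix(c(1, 0, 0, 0), 1, 4)), 1e-9)
  recovered <- quat_multiply(rel$q[1, ], rel0$q)
  expect_lt(quat_maxdiff(recovered, rel$q), 1e-9)

  const <- quat_series(time, matrix(quat_from_axis_angle(c(1, 0, 0), 45), n, 4, byrow = TRUE))
  expect_lt(max(abs(global_motion_angle(express_relative_to_initial(const))$angle)), 1e-9)
})

test_that("global motion angle round-trips axis-angle constructions", {
  set.seed(23)
  angles <- c(0, stats::runif(40, 0, 179), 90, 179.5)
  axis <- c(0.3, -0.8, 0.52)
  q <- quat_from_axis_angle(axis, angles)
  qs <- quat_series(seq_along(angles), q)
  got <- global_motion_angle(qs)$angle
  expect_equal(got, abs(angles), tolerance = 1e-6)
  # sign flip q -> -q leaves the represented motion unchanged
  qs2 <- quat_series(seq_along(angles), -q)
  expect_equal(global_motion_angle(qs2)$angle, got, tolerance = 1e-9)
})

test_that("rmsd matches hand computations and is symmetric", {
  t <- 1:4
  a <- angle_series(t, c(10, 20, 30, 40))
  expect_equal(rmsd_deg(a, a), 0)
  b <- angle_series(t, c(13, 23, 33, 43))
  expect_equal(rmsd_deg(a, b), 3)
  two <- angle_series(1:2, c(0, 0))
  off <- angle_series(1:2, c(3, 4))
  expect_equal(rmsd_deg(two, off), sqrt(12.5))  # 3.5355339...
  expect_equal(rmsd_deg(off, two), rmsd_deg(two, off))
  expect_error(rmsd_deg(a, angle_series(1:3, c(1, 2, 3))), "alignment")
})

test_that("quality labels partition the RMSD axis at 5 and 10 degrees", {
  expect_equal(as.character(label_from_rmsd(c(0.9, 5, 5.0001, 10, 10.01, 50))),
               c("good", "good", "tolerable", "tolerable", "bad", "bad"))
  # every non-negative value gets exactly one category
  grid <- c(seq(0, 20, by = 0.01), 1e6)
  lab <- label_from_rmsd(grid)
  expect_false(anyNA(lab))
  expect_true(all((grid <= 5) == (lab == "good")))
  expect_true(all((grid > 5 & grid <= 10) == (lab == "tolerable")))
  expect_true(all((grid > 10) == (lab == "bad")))
  expect_error(label_from_rmsd(-0.1), "non-negative")
})

test_that("hemisphere continuity removes sign flips without changing rotations", {
  set.seed(24)
  q <- random_quats(30)
  flip <- sample(c(-1, 1), 30, replace = TRUE)
  fixed <- quat_enforce_continuity(q * flip)
  d <- rowSums(fixed[-1, ] * fixed[-30, ])
  expect_true(all(d >= 0))
  expect_lt(quat_maxdiff(fixed, q), 1e-9)
})
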