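# The synthetic TUG cohort generator: kinematic consistency, magnetic
# perturbation and the orientation error model.

test_that("sitting is quiet and speed conditions order the walking intensity", {
  cfg <- cohort_config(n_participants = 1)
  slow <- generate_trial(cfg, speed = 0.7, seed = 61)
  fast <- generate_trial(cfg, speed = 1.4, seed = 61)
  for (trial in list(slow, fast)) {
    sit <- trial$annotations[trial$annotations$phase == "sit", ]
    idx <- seq.int(sit$start + 1L, sit$end)
    for (m in names(trial$modules)) {
      raw <- trial$modules[[m]]$raw[idx, ]
      expect_lt(mean(sqrt(raw$gx^2 + raw$gy^2 + raw$gz^2)), 5)
    }
  }
  walk_norm <- function(trial) {
    w <- trial$annotations[trial$annotations$phase == "walk1", ]
    idx <- seq.int(w$start + 1L, w$end)
    raw <- trial$modules$foot$raw[idx, ]
    mean(sqrt(raw$gx^2 + raw$gy^2 + raw$gz^2))
  }
  expect_gt(walk_norm(fast), walk_norm(slow))
})

test_that("integrating the generated gyro reproduces the true orientation", {
  cfg <- noiseless_config(n_participants = 1)
  trial <- generate_trial(cfg, speed = 1.4, seed = 62)
  for (m in c("torso", "foot")) {
    raw <- trial$modules[[m]]$raw
    omega <- as.matrix(raw[, c("gx", "gy", "gz")])
    n <- nrow(omega)
    dt <- 1 / cfg$rate
    # independent midpoint integrator built from the verified primitives
    q <- c(1, 0, 0, 0)
    worst <- 0
    for (k in seq_len(n - 1)) {
      q <- quat_multiply(q, quat_from_rotvec((omega[k, ] + omega[k + 1, ]) / 2 * dt))
      worst <- max(worst, quat_angle_between(matrix(q, 1), trial$modules[[m]]$truth$q[k + 1, , drop = FALSE]))
    }
    expect_lt(worst, 0.1)
  }
})

test_that("sit-to-stand produces a substantial hip/knee excursion", {
  cfg <- noiseless_config(n_participants = 1)
  trial <- generate_trial(cfg, speed = 1, seed = 63)
  sts <- trial$annotations[trial$annotations$phase == "sit_to_stand", ]
  idx <- seq.int(sts$start + 1L, sts$end)
  for (j in c("hip", "knee")) {
    jd <- trial$joints[[j]]
    rel <- relative_orientation_series(
      quat_series_slice(trial$modules[[jd$prox]]$truth, idx),
      quat_series_slice(trial$modules[[jd$dist]]$truth, idx)
    )
    ang <- global_motion_angle(express_relative_to_initial(rel))$angle
    expect_gt(max(ang), 40)
    expect_lt(max(ang), 110)
  }
})

test_that("magnetic perturbation scales with height and vanishes at zero amplitude", {
  cfg <- cohort_config(n_participants = 1)
  trial <- generate_trial(cfg, seed = 64)
  same <- inject_magnetic_perturbation(trial, cfg, amplitude = 0)
  expect_identical(same$modules$foot$raw$mx, trial$modules$foot$raw$mx)

  pert <- inject_magnetic_perturbation(trial, cfg, amplitude = 1)
  dev <- function(tr, m) {
    raw <- tr$modules[[m]]$raw
    mean(abs(sqrt(raw$mx^2 + raw$my^2 + raw$mz^2) - cfg$mag$reference))
  }
  expect_gt(dev(pert, "foot"), dev(pert, "shank"))
  expect_gt(dev(pert, "shank"), 2 * dev(pert, "torso"))

  # the feature extractor sees the injected inter-module difference
  ann <- pert$annotations
  ann$joint <- "ankle"
  ann$trial_id <- pert$trial_id
  pert$modules$shank$ahrs <- pert$modules$shank$truth
  pert$modules$foot$ahrs <- pert$modules$foot$truth
  seg <- slice_segments(pert, ann[ann$phase == "sit", ])[[1]]
  f <- extract_features(seg, mag_reference = cfg$mag$reference)
  expect_lt(f[["f15"]], -0.1)  # distal (foot) field raised above proximal
})

test_that("orientation error grows with the accuracy drivers", {
  cfg <- noiseless_config(n_participants = 1)
  trial <- generate_trial(cfg, speed = 0.4, seed = 65)

  ankle_sit_rmsd <- function(tr) {
    ann <- tr$annotations[tr$annotations$phase == "sit", ]
    idx <- seq.int(ann$start + 1L, ann$end)
    jd <- tr$joints$ankle
    est <- relative_orientation_series(
      quat_series_slice(tr$modules[[jd$prox]]$ahrs, idx),
      quat_series_slice(tr$modules[[jd$dist]]$ahrs, idx)
    )
    rmsd_deg(global_motion_angle(express_relative_to_initial(est)),
             global_motion_angle(express_relative_to_initial(
               quat_series_slice(jd$ref, idx))))
  }

  # zero drivers: slow, clean, noise-free -> sub-degree accuracy
  clean <- corrupt_orientation(inject_magnetic_perturbation(trial, cfg, amplitude = 0), cfg)
  expect_lt(ankle_sit_rmsd(clean), 1)

  # monotone degradation with disturbance amplitude, all else fixed
  rmsds <- vapply(c(0.3, 0.8, 1.5, cfg$mag$severe_amplitude), function(a) {
    set.seed(66)  # identical jitter draws across amplitudes
    ankle_sit_rmsd(corrupt_orientation(inject_magnetic_perturbation(trial, cfg, amplitude = a), cfg))
  }, numeric(1))
  expect_true(all(diff(rmsds) > 0))

  # the severe preset pushes the ankle past the bad threshold
  expect_gt(rmsds[4], 10)
})

test_that("cohorts have the designed segment count and are seed-reproducible", {
  co <- tiny_cohort()
  expect_identical(n_segments(co), 2L * 9L * 6L * 4L)
  cfg <- cohort_config(n_participants = 1, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_participants = 1, seed = 100))
  expect_false(identical(a, c))
})

test_that("ankle segments are labelled bad far more often than trunk segments", {
  ft <- tiny_feature_table()
  bad_frac <- tapply(ft$label == "bad", ft$joint, mean)
  expect_gt(bad_frac[["ankle"]], bad_frac[["trunk"]] + 0.2)
  expect_true(all(c("good", "tolerable", "bad") %in% ft$label))
})

test_that("feature f15 tracks the injected inter-module field difference", {
  co <- tiny_cohort()
  ft <- tiny_feature_table()
  ft_ankle <- ft[ft$joint == "ankle", ]
  injected <- vapply(seq_len(nrow(ft_ankle)), function(i) {
    tr <- co$trials[[ft_ankle$trial_id[i]]]
    ann <- tr$annotations[tr$annotations$phase == ft_ankle$phase[i], ]
    idx <- seq.int(ann$start + 1L, ann$end)
    mean(tr$disturbance[idx, "shank"] - tr$disturbance[idx, "foot"])
  }, numeric(1))
  expect_gt(cor(ft_ankle$f15, injected, method = "spearman"), 0.9)
})
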