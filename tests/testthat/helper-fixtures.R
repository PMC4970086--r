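# Shared fixtures, built in code. Expensive objects are memoised so several
# test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memoise_fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Two-participant cohort at study-default conditions (18 trials, 432 segments).
tiny_cohort <- function() {
  memoise_fixture("tiny_cohort", function() {
    generate_cohort(cohort_config(n_participants = 2, seed = 7))
  })
}

tiny_feature_table <- function() {
  memoise_fixture("tiny_features", function() cohort_feature_table(tiny_cohort()))
}

# Noise-free configuration: sensors and the orientation error model are exact,
# so kinematic-consistency oracles see only the construction itself.
noiseless_config <- function(...) {
  cohort_config(noise = list(accel_sd = 0, gyro_sd = 0, mag_sd = 0),
                error = list(drift_gain = 8, vel_gain = 0.1, omega0 = 180,
                             drift_jitter_sd = 0.3, base_drift_sd = 0,
                             quat_noise_sd_deg = 0),
                ref_offset_max = 0, ...)
}

# Build an imu_segment directly from channel vectors (defaults: static module,
# level, magnetometer reading the unit reference field).
make_raw <- function(n = 10, ax = 0, ay = 0, az = 1, gx = 0, gy = 0, gz = 0,
                     mx = 1, my = 0, mz = 0) {
  data.frame(time = (seq_len(n) - 1) / 60,
             ax = rep_len(ax, n), ay = rep_len(ay, n), az = rep_len(az, n),
             gx = rep_len(gx, n), gy = rep_len(gy, n), gz = rep_len(gz, n),
             mx = rep_len(mx, n), my = rep_len(my, n), mz = rep_len(mz, n))
}

make_segment <- function(raw_prox = make_raw(), raw_dist = make_raw(),
                         phase = "sit", joint = "ankle") {
  structure(list(trial_id = "T1", phase = phase, joint = joint,
                 time = raw_prox$time, raw_prox = raw_prox, raw_dist = raw_dist),
            class = "imu_segment")
}

# Random unit quaternions, uniformly distributed (Marsaglia-style via normals).
random_quats <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# Independent quaternion angle between two unit quaternions, degrees.
quat_angle_between <- function(a, b) {
  d <- pmin(abs(rowSums(as.matrix(a) * as.matrix(b))), 1)
  2 * acos(d) * 180 / pi
}

# Largest component-wise discrepancy between quaternion batches, up to the
# q/-q sign ambiguity. Sharper than the acos-based angle near zero.
quat_maxdiff <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  max(pmin(apply(abs(a - b), 1, max), apply(abs(a + b), 1, max)))
}
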