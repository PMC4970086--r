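# Synthetic timed-up-and-go (TUG) cohorts.
#
# The generator produces, for every trial, a kinematically consistent set of
# body-segment module streams: a true body angular-velocity profile per
# module, the true orientation obtained by midpoint integration of that
# profile, raw 9-axis sensor signals derived from the true kinematics, and
# AHRS orientation estimates corrupted by a parametric error model. The AHRS
# fusion filter itself is deliberately not simulated: the quality-control
# method consumes AHRS output as a black box, so the error model directly
# encodes the two accuracy drivers it must learn to recognize — persistent
# inter-module magnetic-field differences (heading drift) and angular
# velocity beyond the fusion filter's comfortable range.

tug_modules <- function() c("torso", "pelvis", "thigh", "shank", "foot")

tug_joints <- function() {
  list(
    trunk = list(prox = "torso", dist = "pelvis"),
    hip   = list(prox = "pelvis", dist = "thigh"),
    knee  = list(prox = "thigh", dist = "shank"),
    ankle = list(prox = "shank", dist = "foot")
  )
}

tug_phases <- function() c("sit", "sit_to_stand", "walk1", "walk2", "turn", "turn_to_sit")

# Module mounting heights above the floor (m) and motion scale constants.
module_heights <- function() {
  c(torso = 1.30, pelvis = 1.00, thigh = 0.70, shank = 0.35, foot = 0.05)
}
walk_amplitude_deg <- function() {
  c(torso = 4, pelvis = 6, thigh = 25, shank = 50, foot = 60)
}
sts_excursion_deg <- function() {
  c(torso = 25, pelvis = 10, thigh = 80, shank = 15, foot = 5)
}
# How strongly the floor-level disturbance field is felt in each phase: the
# chair area (sit, transfers) sits over the disturbed region, the walkway
# less so.
phase_location_factor <- function() {
  c(sit = 1, sit_to_stand = 1, walk1 = 0.4, walk2 = 0.4, turn = 0.25,
    turn_to_sit = 0.9)
}

#' Configuration of a synthetic TUG cohort
#'
#' Defaults follow the study design the generator emulates: 20 participants,
#' 9 trials each (3 speed conditions x 3 repetitions), 6 task phases, 4
#' joints tracked by 5 body-segment modules, raw signals at 60 Hz.
#'
#' @param n_participants Number of participants.
#' @param reps Repetitions per speed condition.
#' @param speeds Speed condition factors; durations divide by the factor and
#'   movement cadence multiplies with it.
#' @param rate Raw sampling rate in Hz.
#' @param seed Cohort seed; generation is fully deterministic given the seed.
#' @param phase_durations Named natural-speed phase durations in seconds.
#' @param mag Magnetic-environment model: `reference` field magnitude,
#'   `amplitude_max` (per-trial disturbance amplitude is uniform on
#'   `[0, amplitude_max]`), `severe_amplitude` (preset guaranteeing bad
#'   ankle segments), `decay` (spatial decay length of the floor field, m),
#'   `wobble` (slow relative modulation of the disturbance).
#' @param error AHRS error model: `drift_gain` (deg/s heading drift per unit
#'   field disturbance), `vel_gain` (deg/s drift per deg/s of angular speed
#'   beyond `omega0`), `omega0` (deg/s velocity threshold),
#'   `drift_jitter_sd` (log-SD of per-trial, per-module gain jitter standing
#'   in for disturbance-geometry variation), `base_drift_sd` (half-normal SD
#'   of a small ever-present per-module heading drift, deg/s,
#'   representing residual fusion error), `quat_noise_sd_deg` (white
#'   orientation noise).
#' @param noise Sensor noise SDs: `accel_sd` (g), `gyro_sd` (deg/s),
#'   `mag_sd` (field units).
#' @param participant Ranges of the per-participant uniform scale factors on
#'   movement amplitude and cadence (anthropometric heterogeneity).
#' @param ref_offset_max Maximum clock offset (in raw samples) between the
#'   reference system and the AHRS streams, resolved later by
#'   cross-correlation synchronization.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20L,
                          reps = 3L,
                          speeds = c(slow = 0.7, natural = 1.0, fast = 1.4),
                          rate = 60,
                          seed = 42L,
                          phase_durations = c(sit = 3, sit_to_stand = 1.5,
                                              walk1 = 3, walk2 = 3, turn = 2,
                                              turn_to_sit = 2.5),
                          mag = list(reference = 1, amplitude_max = 1.5,
                                     severe_amplitude = 2.5, decay = 0.3,
                                     wobble = 0.1),
                          error = list(drift_gain = 8, vel_gain = 0.1,
                                       omega0 = 180, drift_jitter_sd = 0.3,
                                       base_drift_sd = 0.4,
                                       quat_noise_sd_deg = 0.3),
                          noise = list(accel_sd = 0.02, gyro_sd = 1.0,
                                       mag_sd = 0.01),
                          participant = list(amp_range = c(0.85, 1.15),
                                             cadence_range = c(0.9, 1.1)),
                          ref_offset_max = 5L) {
  stopifnot(n_participants > 0, reps > 0, rate > 0, all(speeds > 0),
            all(phase_durations > 0), mag$amplitude_max >= 0, mag$decay > 0,
            mag$reference > 0, error$drift_gain >= 0, error$vel_gain >= 0,
            error$omega0 >= 0, ref_offset_max >= 0)
  if (!identical(sort(names(phase_durations)), sort(tug_phases()))) {
    stop("config error: phase_durations must name exactly the phases ",
         paste(tug_phases(), collapse = ", "))
  }
  structure(list(
    n_participants = as.integer(n_participants), reps = as.integer(reps),
    speeds = speeds, rate = rate, seed = as.integer(seed),
    phase_durations = phase_durations[tug_phases()], mag = mag, error = error,
    noise = noise, participant = participant,
    ref_offset_max = as.integer(ref_offset_max)
  ), class = "cohort_config")
}

# Phase boundaries (0-based, half-open) for one trial at a speed condition.
trial_timeline <- function(cfg, speed) {
  dur <- cfg$phase_durations / speed
  n_ph <- pmax(2L, as.integer(round(dur * cfg$rate)))
  end <- cumsum(n_ph)
  data.frame(phase = names(dur), start = c(0L, end[-length(end)]), end = end,
             stringsAsFactors = FALSE)
}

# Half-sine-squared pulse integrating to `excursion` degrees over [0, T].
pulse_rate <- function(tau, T, excursion) {
  (2 * excursion / T) * sin(pi * tau / T)^2
}

# True body angular velocity (deg/s), n x 3, for one module across the trial.
module_omega <- function(module, tl, time, cfg, speed, factors, sway) {
  n <- length(time)
  w <- matrix(0, n, 3L)
  A <- walk_amplitude_deg()[[module]] * factors$amp
  E <- sts_excursion_deg()[[module]] * factors$amp
  f <- 0.9 * speed * factors$cadence
  for (i in seq_len(nrow(tl))) {
    idx <- seq.int(tl$start[i] + 1L, tl$end[i])
    tau <- time[idx] - time[idx[1L]]
    T <- tau[length(tau)] + 1 / cfg$rate
    ph <- tl$phase[i]
    if (ph %in% c("walk1", "walk2")) {
      w[idx, 1] <- w[idx, 1] + A * 2 * pi * f * cos(2 * pi * f * tau)
      w[idx, 2] <- w[idx, 2] + 0.35 * A * 2 * pi * f * cos(2 * pi * f * tau + 1)
      w[idx, 3] <- w[idx, 3] + 0.15 * A * 2 * pi * f * sin(2 * pi * f * tau)
    } else if (ph == "sit_to_stand") {
      w[idx, 1] <- w[idx, 1] + pulse_rate(tau, T, E)
    } else if (ph == "turn") {
      w[idx, 3] <- w[idx, 3] + pulse_rate(tau, T, 180)
      w[idx, 1] <- w[idx, 1] + 0.4 * A * 2 * pi * f * cos(2 * pi * f * tau)
    } else if (ph == "turn_to_sit") {
      w[idx, 3] <- w[idx, 3] + pulse_rate(tau, T, 180)
      w[idx, 1] <- w[idx, 1] - pulse_rate(tau, T, E)
      w[idx, 2] <- w[idx, 2] + 0.3 * A * 2 * pi * f * cos(2 * pi * f * tau)
    }
    # sit: postural sway only
  }
  # slow postural sway on every axis throughout the trial
  for (ax in 1:3) {
    w[, ax] <- w[, ax] + sway$amp[ax] * sin(2 * pi * sway$freq[ax] * time + sway$phase[ax])
  }
  w
}

# Midpoint integration of body rates into a world-from-body quaternion
# sequence starting at identity.
integrate_gyro <- function(time, omega_deg) {
  n <- length(time)
  q <- matrix(0, n, 4L)
  q[1L, ] <- c(1, 0, 0, 0)
  if (n > 1L) {
    dt <- diff(time)
    step <- quat_from_rotvec((omega_deg[-n, , drop = FALSE] +
                              omega_deg[-1L, , drop = FALSE]) / 2 * dt)
    if (is.null(dim(step))) step <- matrix(step, nrow = 1L)
    for (k in seq_len(n - 1L)) {
      a <- q[k, ]; b <- step[k, ]
      p <- c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
             a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
             a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
             a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
      q[k + 1L, ] <- p / sqrt(sum(p^2))
    }
  }
  q
}

world_mag_direction <- function() {
  dip <- 60 * pi / 180
  c(cos(dip), 0, -sin(dip))
}

#' Generate one ground-truth TUG trial
#'
#' Builds smooth phase-wise angular-velocity profiles for the five
#' body-segment modules (near-still sitting, a sit-to-stand flexion pulse
#' with 60-100 degree hip/knee excursion, periodic walking with cadence and
#' amplitude scaled by the speed condition, a 180 degree turn, and a combined
#' turn-to-sit), integrates them into true orientations, and derives raw
#' sensor signals (gyro = rates + noise; accel = gravity + a motion-scaled
#' dynamic component + noise; magnetometer = the rotated world field + noise,
#' undisturbed at this stage). Distal modules receive proportionally higher
#' angular velocities. Gold-standard joint orientation series are computed
#' from the true module orientations and offset by a random few-sample clock
#' lag. Randomness is drawn from the current RNG state unless `seed` is
#' given.
#'
#' @param cfg A [cohort_config].
#' @param participant Participant number (bookkeeping only).
#' @param trial_index Trial number within the participant (bookkeeping only).
#' @param speed Speed condition factor.
#' @param factors List with per-participant `amp` and `cadence` scale
#'   factors; default unit scales.
#' @param seed Optional seed for standalone use.
#' @return Object of class `imu_trial`.
#' @export
generate_trial <- function(cfg, participant = 1L, trial_index = 1L, speed = 1,
                           factors = list(amp = 1, cadence = 1), seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(seed)) {
    return(with_local_seed(seed, generate_trial(cfg, participant, trial_index,
                                                speed, factors)))
  }
  tl <- trial_timeline(cfg, speed)
  n <- tl$end[nrow(tl)]
  time <- (seq_len(n) - 1L) / cfg$rate
  u_mag <- world_mag_direction() * cfg$mag$reference

  modules <- list()
  for (m in tug_modules()) {
    sway <- list(amp = stats::runif(3, 0.5, 1.5),
                 freq = stats::runif(3, 0.2, 0.5),
                 phase = stats::runif(3, 0, 2 * pi))
    omega <- module_omega(m, tl, time, cfg, speed, factors, sway)
    q <- integrate_gyro(time, omega)
    qc <- quat_conjugate(q)
    grav <- quat_rotate_vector(qc, c(0, 0, 1))
    spd <- sqrt(rowSums(omega^2))
    th <- 2 * pi * 1.8 * speed * time + stats::runif(1, 0, 2 * pi)
    dyn <- (0.001 * spd) * cbind(sin(th), cos(th), 0.3) / sqrt(1.09)
    accel <- grav + dyn +
      matrix(stats::rnorm(3L * n, 0, cfg$noise$accel_sd), n, 3L)
    gyro <- omega + matrix(stats::rnorm(3L * n, 0, cfg$noise$gyro_sd), n, 3L)
    mag <- quat_rotate_vector(qc, u_mag) +
      matrix(stats::rnorm(3L * n, 0, cfg$noise$mag_sd), n, 3L)
    raw <- data.frame(time = time,
                      ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                      gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                      mx = mag[, 1], my = mag[, 2], mz = mag[, 3])
    modules[[m]] <- list(raw = raw, truth = quat_series(time, q))
  }

  ref_offset <- if (cfg$ref_offset_max > 0) {
    sample.int(2L * cfg$ref_offset_max + 1L, 1L) - cfg$ref_offset_max - 1L
  } else 0L
  joints <- tug_joints()
  for (j in names(joints)) {
    ref <- quat_multiply(quat_conjugate(modules[[joints[[j]]$prox]]$truth$q),
                         modules[[joints[[j]]$dist]]$truth$q)
    joints[[j]]$ref <- quat_series(time, shift_by_lag(ref, -ref_offset))
  }

  annotations <- data.frame(trial_id = sprintf("P%02d_T%d", participant, trial_index),
                            phase = tl$phase, start = tl$start, end = tl$end,
                            stringsAsFactors = FALSE)
  structure(list(
    trial_id = sprintf("P%02d_T%d", participant, trial_index),
    participant = as.integer(participant), trial_index = as.integer(trial_index),
    speed = speed, rate = cfg$rate, time = time,
    modules = modules, joints = joints, annotations = annotations,
    disturbance = matrix(0, n, length(tug_modules()),
                         dimnames = list(NULL, tug_modules())),
    meta = list(factors = factors, ref_offset = ref_offset)
  ), class = "imu_trial")
}

#' Inject a floor-proximal magnetic disturbance into a trial
#'
#' The disturbance field decays exponentially with module height above the
#' floor, so ankle-level modules are perturbed far more than trunk-level
#' ones; it is strongest around the chair area (sit and transfer phases) and
#' weaker along the walkway. Magnetometer signals are scaled by
#' `1 + disturbance`, so a zero amplitude leaves them unchanged and
#' unperturbed modules keep their field magnitude at the reference value.
#'
#' @param trial An `imu_trial` from [generate_trial].
#' @param cfg The [cohort_config].
#' @param amplitude Disturbance amplitude; `NULL` draws uniformly on
#'   `[0, mag$amplitude_max]` from the current RNG state.
#' @return The trial with perturbed magnetometer channels and the disturbance
#'   profile stored in `$disturbance`.
#' @export
inject_magnetic_perturbation <- function(trial, cfg, amplitude = NULL) {
  stopifnot(inherits(trial, "imu_trial"), inherits(cfg, "cohort_config"))
  if (is.null(amplitude)) amplitude <- stats::runif(1, 0, cfg$mag$amplitude_max)
  stopifnot(amplitude >= 0)
  loc <- phase_location_factor()
  loc_t <- numeric(length(trial$time))
  for (i in seq_len(nrow(trial$annotations))) {
    idx <- seq.int(trial$annotations$start[i] + 1L, trial$annotations$end[i])
    loc_t[idx] <- loc[[trial$annotations$phase[i]]]
  }
  wob <- 1 + cfg$mag$wobble * sin(2 * pi * 0.1 * trial$time +
                                  stats::runif(1, 0, 2 * pi))
  h <- module_heights()
  for (m in tug_modules()) {
    d <- amplitude * exp(-h[[m]] / cfg$mag$decay) * loc_t * wob
    scale <- 1 + d
    trial$modules[[m]]$raw$mx <- trial$modules[[m]]$raw$mx * scale
    trial$modules[[m]]$raw$my <- trial$modules[[m]]$raw$my * scale
    trial$modules[[m]]$raw$mz <- trial$modules[[m]]$raw$mz * scale
    trial$disturbance[, m] <- d
  }
  trial$meta$mag_amplitude <- amplitude
  trial
}

#' Corrupt true orientations into AHRS estimates
#'
#' Each module's estimate is the true orientation composed with a heading
#' (vertical-axis) error, the axis the magnetometer constrains. The drift
#' rate is `drift_gain * disturbance + vel_gain * max(0, |gyro| - omega0)`,
#' scaled by a per-trial, per-module log-normal jitter that stands in for
#' varying disturbance geometry, and accumulated over the trial; small white
#' orientation noise is added on top. Slow, magnetically clean trials
#' therefore stay accurate while disturbed or fast segments degrade, spanning
#' the good / tolerable / bad range across a cohort.
#'
#' @param trial An `imu_trial`, after [inject_magnetic_perturbation].
#' @param cfg The [cohort_config].
#' @return The trial with an `ahrs` [quat_series] added to every module.
#' @export
corrupt_orientation <- function(trial, cfg) {
  stopifnot(inherits(trial, "imu_trial"), inherits(cfg, "cohort_config"))
  n <- length(trial$time)
  dt <- 1 / trial$rate
  for (m in tug_modules()) {
    mod <- trial$modules[[m]]
    jitter <- exp(stats::rnorm(1, 0, cfg$error$drift_jitter_sd))
    base <- abs(stats::rnorm(1, 0, cfg$error$base_drift_sd))
    gyro_mag <- sqrt(mod$raw$gx^2 + mod$raw$gy^2 + mod$raw$gz^2)
    rate <- base + jitter * (cfg$error$drift_gain * trial$disturbance[, m] +
                             cfg$error$vel_gain * pmax(0, gyro_mag - cfg$error$omega0))
    delta <- cumsum(rate) * dt   # heading error in degrees
    half <- delta * pi / 360
    zrot <- cbind(cos(half), 0, 0, sin(half))
    est <- quat_multiply(zrot, mod$truth$q)
    if (cfg$error$quat_noise_sd_deg > 0) {
      noise <- quat_from_rotvec(matrix(
        stats::rnorm(3L * n, 0, cfg$error$quat_noise_sd_deg), n, 3L))
      est <- quat_multiply(est, noise)
    }
    trial$modules[[m]]$ahrs <- quat_series(trial$time, est)
    trial$modules[[m]]$drift_deg <- delta
  }
  trial
}

#' Generate a full synthetic cohort
#'
#' Deterministic given `cfg$seed`: participants receive seeded anthropometric
#' scale factors, and every trial is generated, magnetically perturbed and
#' corrupted in a fixed order. Each participant contributes
#' `reps * length(speeds)` trials of 6 phases x 4 joints.
#'
#' @param cfg A [cohort_config].
#' @param out_dir Optional directory; when given the cohort is also written
#'   as CSV files via [write_cohort].
#' @return Object of class `imu_cohort`: `config`, `trials` (list of
#'   `imu_trial`), `annotations` (per-joint segment table, 0-based half-open
#'   indices at the raw rate).
#' @export
generate_cohort <- function(cfg = cohort_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  cohort <- with_local_seed(cfg$seed, {
    trials <- list()
    for (p in seq_len(cfg$n_participants)) {
      factors <- list(
        amp = stats::runif(1, cfg$participant$amp_range[1], cfg$participant$amp_range[2]),
        cadence = stats::runif(1, cfg$participant$cadence_range[1],
                               cfg$participant$cadence_range[2])
      )
      idx <- 0L
      for (speed in cfg$speeds) {
        for (r in seq_len(cfg$reps)) {
          idx <- idx + 1L
          tr <- generate_trial(cfg, p, idx, speed, factors)
          tr <- inject_magnetic_perturbation(tr, cfg)
          tr <- corrupt_orientation(tr, cfg)
          trials[[tr$trial_id]] <- tr
        }
      }
    }
    trials
  })
  annotations <- do.call(rbind, lapply(cohort, function(tr) {
    merge(tr$annotations, data.frame(joint = names(tug_joints())), by = NULL)
  }))
  annotations <- annotations[, c("trial_id", "phase", "joint", "start", "end")]
  rownames(annotations) <- NULL
  out <- structure(list(config = cfg, trials = cohort, annotations = annotations),
                   class = "imu_cohort")
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' Number of joint-segments in a cohort
#'
#' @param cohort An `imu_cohort`.
#' @return Integer: trials x phases x joints.
#' @export
n_segments <- function(cohort) {
  stopifnot(inherits(cohort, "imu_cohort"))
  nrow(cohort$annotations)
}

#' @export
print.imu_cohort <- function(x, ...) {
  cat(sprintf("<imu_cohort> %d participants, %d trials, %d joint-segments\n",
              x$config$n_participants, length(x$trials), n_segments(x)))
  invisible(x)
}
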