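# End-to-end driver: prep -> label -> features -> normalize -> train ->
# validate -> report.

#' Prepare one trial: resample and synchronize
#'
#' Resamples every stream (raw, AHRS, reference) onto a uniform grid at
#' `target_hz`, rescales the phase annotations to the new grid, and aligns
#' the reference streams to the AHRS streams with an integer-lag
#' cross-correlation on the global-motion angle of the most mobile joint
#' (the one with the highest angular-velocity variance). The correlation is
#' computed on the sample-to-sample angle increments: differencing removes
#' the slow heading drift that may contaminate the AHRS estimate, so the
#' alignment keys on genuine motion.
#'
#' @param trial An `imu_trial` with `ahrs` streams.
#' @param target_hz Target sampling rate (Hz).
#' @param max_lag Synchronization search range in samples at `target_hz`.
#' @return The prepared `imu_trial`; `meta$sync_lag` records the applied lag.
#' @export
prep_trial <- function(trial, target_hz = 100, max_lag = 20L) {
  stopifnot(inherits(trial, "imu_trial"))
  old_rate <- trial$rate
  for (m in names(trial$modules)) {
    trial$modules[[m]]$raw <- resample_linear(trial$modules[[m]]$raw, target_hz)
    trial$modules[[m]]$ahrs <- resample_quat_series(trial$modules[[m]]$ahrs, target_hz)
    trial$modules[[m]]$truth <- NULL
  }
  for (j in names(trial$joints)) {
    trial$joints[[j]]$ref <- resample_quat_series(trial$joints[[j]]$ref, target_hz)
  }
  trial$time <- trial$modules[[1L]]$raw$time
  trial$rate <- target_hz
  n_new <- length(trial$time)
  trial$annotations$start <- pmin(round(trial$annotations$start / old_rate * target_hz), n_new - 1L)
  trial$annotations$end <- pmin(round(trial$annotations$end / old_rate * target_hz), n_new)

  est_angle <- lapply(names(trial$joints), function(j) {
    jd <- trial$joints[[j]]
    rel <- relative_orientation_series(trial$modules[[jd$prox]]$ahrs,
                                       trial$modules[[jd$dist]]$ahrs)
    global_motion_angle(express_relative_to_initial(rel))$angle
  })
  names(est_angle) <- names(trial$joints)
  mobility <- vapply(est_angle, function(a) stats::var(diff(a)), numeric(1))
  sync_joint <- names(which.max(mobility))
  ref_angle <- global_motion_angle(express_relative_to_initial(
    trial$joints[[sync_joint]]$ref))$angle
  lag <- xcorr_sync(diff(est_angle[[sync_joint]]), diff(ref_angle),
                    max_lag = max_lag)
  for (j in names(trial$joints)) {
    trial$joints[[j]]$ref <- quat_series(trial$time,
                                         shift_by_lag(trial$joints[[j]]$ref$q, lag))
  }
  trial$meta$sync_lag <- lag
  trial$meta$sync_joint <- sync_joint
  trial
}

segment_rmsd <- function(segment) {
  est_rel <- relative_orientation_series(segment$ahrs_prox, segment$ahrs_dist)
  est <- global_motion_angle(express_relative_to_initial(est_rel))
  ref <- global_motion_angle(express_relative_to_initial(segment$ref_joint))
  rmsd_deg(est, ref)
}

#' Feature/label table of one prepared trial
#'
#' Slices the trial into its 6 phases x 4 joints, computes the 16 features of
#' every segment (chaining the previous segment of the same joint for f16),
#' the RMSD of the AHRS global joint motion against the reference, and the
#' quality label.
#'
#' @param trial A prepared `imu_trial` (see [prep_trial]).
#' @param mag_reference Calibration magnetic-field magnitude for the
#'   deviation features.
#' @return Data frame, one row per segment: identifiers, `f1`..`f16`,
#'   `rmsd`, `label`.
#' @export
trial_feature_table <- function(trial, mag_reference = 1) {
  stopifnot(inherits(trial, "imu_trial"))
  rows <- list()
  for (j in names(trial$joints)) {
    ann <- trial$annotations
    ann <- ann[match(tug_phases(), ann$phase), ]
    ann$joint <- j
    segs <- slice_segments(trial, ann)
    prev <- NULL
    for (k in seq_along(segs)) {
      seg <- segs[[k]]
      feats <- extract_features(seg, previous = prev, mag_reference = mag_reference)
      rmsd <- segment_rmsd(seg)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = trial$trial_id, participant = trial$participant,
        speed = trial$speed, phase = seg$phase, joint = seg$joint,
        t(feats), rmsd = rmsd, label = label_from_rmsd(rmsd),
        f16_imputed = attr(feats, "f16_imputed"), stringsAsFactors = FALSE
      )
      prev <- seg
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature/label table of a whole cohort
#'
#' Runs [prep_trial] and [trial_feature_table] over every trial.
#'
#' @param cohort An `imu_cohort` (in memory or from [read_cohort]).
#' @param target_hz Resampling rate.
#' @param max_lag Synchronization search range.
#' @param mag_reference Calibration magnetic-field magnitude.
#' @return Data frame with one row per joint-segment.
#' @export
cohort_feature_table <- function(cohort, target_hz = 100, max_lag = 20L,
                                 mag_reference = 1) {
  stopifnot(inherits(cohort, "imu_cohort"))
  tables <- lapply(cohort$trials, function(tr) {
    trial_feature_table(prep_trial(tr, target_hz, max_lag), mag_reference)
  })
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out
}

#' Participant-level train/validation split
#'
#' @param participants Vector of participant identifiers.
#' @param seed Seed for the shuffle.
#' @param train_fraction Fraction assigned to training (default half).
#' @return List with `train` and `validation` participant vectors.
#' @export
split_participants <- function(participants, seed = 1L, train_fraction = 0.5) {
  participants <- unique(participants)
  if (length(participants) < 2L) stop("need at least 2 participants to split")
  shuffled <- with_local_seed(seed, sample(participants))
  n_train <- max(1L, floor(length(participants) * train_fraction))
  list(train = sort(shuffled[seq_len(n_train)]),
       validation = sort(shuffled[-seq_len(n_train)]))
}

#' Run the full quality-control pipeline
#'
#' prep -> label -> features -> normalize (fitted on the training half only)
#' -> train -> predict on the validation half -> report. The split is always
#' at participant level; a segment-level split would leak participant
#' idiosyncrasies between partitions.
#'
#' @param data An `imu_cohort` or a directory readable by [read_cohort].
#' @param split_seed Seed for the participant shuffle.
#' @param train_config A [qc_training_config] for the network fit.
#' @param split Optional explicit list with `train` and `validation`
#'   participant vectors; they must not overlap.
#' @param target_hz,max_lag,mag_reference Passed to [cohort_feature_table].
#' @return Object of class `qc_pipeline_result`: the fitted `model`
#'   (network + normalizer + gains), the annotated `features` table
#'   (with `partition`, `score`, `accepted`), the `split`, training and
#'   validation `metrics`, and the validation pre/post `table`.
#' @export
run_pipeline <- function(data, split_seed = 1L,
                         train_config = qc_training_config(),
                         split = NULL, target_hz = 100, max_lag = 20L,
                         mag_reference = 1) {
  cohort <- if (is.character(data)) read_cohort(data) else data
  stopifnot(inherits(cohort, "imu_cohort"))
  features <- cohort_feature_table(cohort, target_hz, max_lag, mag_reference)

  participants <- unique(features$participant)
  if (is.null(split)) split <- split_participants(participants, split_seed)
  leak <- intersect(split$train, split$validation)
  if (length(leak)) {
    stop("split leak: participants in both partitions: ", paste(leak, collapse = ", "))
  }
  if (!all(participants %in% c(split$train, split$validation))) {
    stop("split must cover every participant")
  }
  features$partition <- ifelse(features$participant %in% split$train,
                               "train", "validation")

  fcols <- feature_names()
  is_train <- features$partition == "train"
  normalizer <- fit_normalizer(features[is_train, fcols])
  X <- apply_normalizer(normalizer, features[, fcols])
  fit <- train_qc_network(X[is_train, , drop = FALSE], features$label[is_train],
                          train_config)
  features$score <- nn_forward(fit$network, X)
  features$accepted <- features$score > 0

  metric_pair <- function(rows) {
    cc <- confusion_counts(features$label[rows], features$accepted[rows])
    list(sensitivity = sensitivity(cc), specificity = specificity(cc),
         counts = cc)
  }
  metrics <- list(training = metric_pair(is_train),
                  validation = metric_pair(!is_train))
  table <- pre_post_table(features[!is_train, ])

  structure(list(
    model = list(network = fit$network, normalizer = normalizer,
                 gains = fit$report$gains, mag_reference = mag_reference,
                 config = list(seed = train_config$seed,
                               lambda = fit$report$lambda,
                               method = train_config$method)),
    train_report = fit$report,
    features = features,
    split = split,
    metrics = metrics,
    table = table
  ), class = "qc_pipeline_result")
}

#' @export
print.qc_pipeline_result <- function(x, ...) {
  cat("Quality-control pipeline result\n")
  cat(sprintf("  training:   %d participants, sensitivity %.3f, specificity %.3f\n",
              length(x$split$train), x$metrics$training$sensitivity,
              x$metrics$training$specificity))
  cat(sprintf("  validation: %d participants, sensitivity %.3f, specificity %.3f\n",
              length(x$split$validation), x$metrics$validation$sensitivity,
              x$metrics$validation$specificity))
  cat("\nValidation pre/post-QC accuracy per task and joint:\n")
  print(x$table)
  invisible(x)
}
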