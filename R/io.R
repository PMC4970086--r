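# Plain-CSV persistence of cohorts, streams and feature tables.
#
# Layouts:
#   quaternion CSV:  time,w,x,y,z          (time in seconds, scalar-first)
#   raw IMU CSV:     time,ax,ay,az,gx,gy,gz,mx,my,mz
#   annotations CSV: trial_id,phase,joint,start,end   (0-based, half-open)
#   feature CSV:     trial_id,participant,speed,phase,joint,f1..f16,rmsd,label

#' Read / write a quaternion series CSV
#'
#' @param path CSV file with header `time,w,x,y,z`.
#' @return A [quat_series].
#' @export
read_quat_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time", "w", "x", "y", "z")
  if (!all(req %in% names(df))) stop("quaternion CSV needs columns time,w,x,y,z: ", path)
  quat_series(df$time, as.matrix(df[, c("w", "x", "y", "z")]))
}

#' @rdname read_quat_csv
#' @param qs A [quat_series] to write.
#' @export
write_quat_csv <- function(qs, path) {
  stopifnot(inherits(qs, "quat_series"))
  df <- data.frame(time = qs$time, w = qs$q[, 1], x = qs$q[, 2],
                   y = qs$q[, 3], z = qs$q[, 4])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

imu_columns <- function() c("time", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' Read / write a raw IMU stream CSV
#'
#' @param path CSV file with header `time,ax,ay,az,gx,gy,gz,mx,my,mz`.
#' @return Data frame with those columns.
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(imu_columns() %in% names(df))) {
    stop("raw IMU CSV needs columns ", paste(imu_columns(), collapse = ","), ": ", path)
  }
  if (any(diff(df$time) <= 0)) stop("ingestion error: non-monotonic timestamps in ", path)
  df[, imu_columns()]
}

#' @rdname read_imu_csv
#' @param raw Data frame of raw IMU samples to write.
#' @export
write_imu_csv <- function(raw, path) {
  utils::write.csv(raw[, imu_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Read a segment-annotation CSV
#'
#' @param path CSV with columns `trial_id,phase,joint,start,end`; indices are
#'   0-based sample indices, half-open `[start, end)`.
#' @return Validated data frame.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df)
  df
}

#' Write a cohort as plain CSV files
#'
#' Creates `trials.csv`, `annotations.csv` and per-trial stream files under
#' `raw/`, `ahrs/` and `ref/`.
#'
#' @param cohort An `imu_cohort`.
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "imu_cohort"))
  for (d in file.path(dir, c("raw", "ahrs", "ref"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  meta <- do.call(rbind, lapply(cohort$trials, function(tr) {
    data.frame(trial_id = tr$trial_id, participant = tr$participant,
               trial_index = tr$trial_index, speed = tr$speed, rate = tr$rate)
  }))
  utils::write.csv(meta, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(cohort$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  for (tr in cohort$trials) {
    for (m in names(tr$modules)) {
      write_imu_csv(tr$modules[[m]]$raw,
                    file.path(dir, "raw", sprintf("%s_%s.csv", tr$trial_id, m)))
      if (!is.null(tr$modules[[m]]$ahrs)) {
        write_quat_csv(tr$modules[[m]]$ahrs,
                       file.path(dir, "ahrs", sprintf("%s_%s.csv", tr$trial_id, m)))
      }
    }
    for (j in names(tr$joints)) {
      write_quat_csv(tr$joints[[j]]$ref,
                     file.path(dir, "ref", sprintf("%s_%s.csv", tr$trial_id, j)))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort]
#'
#' Ground-truth orientations are not persisted (a real recording would not
#' have them); the returned trials carry raw, AHRS and reference streams,
#' which is all the pipeline needs.
#'
#' @param dir Directory produced by [write_cohort].
#' @return An `imu_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  annotations <- read_annotations_csv(file.path(dir, "annotations.csv"))
  trials <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$trial_id[i]
    modules <- list()
    for (m in tug_modules()) {
      modules[[m]] <- list(
        raw = read_imu_csv(file.path(dir, "raw", sprintf("%s_%s.csv", id, m))),
        ahrs = read_quat_csv(file.path(dir, "ahrs", sprintf("%s_%s.csv", id, m)))
      )
    }
    joints <- tug_joints()
    for (j in names(joints)) {
      joints[[j]]$ref <- read_quat_csv(file.path(dir, "ref", sprintf("%s_%s.csv", id, j)))
    }
    ann <- annotations[annotations$trial_id == id & annotations$joint == "trunk", ]
    trials[[id]] <- structure(list(
      trial_id = id, participant = meta$participant[i],
      trial_index = meta$trial_index[i], speed = meta$speed[i],
      rate = meta$rate[i], time = modules[[1L]]$raw$time,
      modules = modules, joints = joints,
      annotations = ann[, c("trial_id", "phase", "start", "end")],
      disturbance = NULL, meta = list()
    ), class = "imu_trial")
  }
  structure(list(config = NULL, trials = trials,
                 annotations = annotations), class = "imu_cohort")
}

#' Write a feature table CSV
#'
#' @param features Feature table from [cohort_feature_table].
#' @param path Output CSV path.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path CSV written by [write_feature_csv].
#' @return Data frame with `label` restored as a factor.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(df)) {
    df$label <- factor(df$label, levels = c("good", "tolerable", "bad"))
  }
  df
}
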