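# Resampling, cross-correlation synchronization and segmentation.

#' Resample a multichannel time series by linear interpolation
#'
#' All non-time columns are interpolated onto a uniform grid spanning the
#' original time range. Used to bring 60 Hz sensor streams onto the 100 Hz
#' grid of the reference system before comparison.
#'
#' @param series Data frame with a numeric `time` column (seconds, strictly
#'   increasing) plus one column per channel.
#' @param target_hz Target sampling rate in Hz.
#' @param time_col Name of the time column.
#' @return Data frame on the new uniform grid, same channel columns.
#' @export
resample_linear <- function(series, target_hz, time_col = "time") {
  stopifnot(is.data.frame(series), target_hz > 0)
  t_old <- series[[time_col]]
  if (is.null(t_old) || length(t_old) < 2L) stop("need at least 2 samples to resample")
  if (any(diff(t_old) <= 0)) stop("ingestion error: non-monotonic timestamps")
  t_new <- seq(t_old[1L], t_old[length(t_old)], by = 1 / target_hz)
  out <- data.frame(time = t_new)
  for (col in setdiff(names(series), time_col)) {
    out[[col]] <- stats::approx(t_old, series[[col]], xout = t_new)$y
  }
  names(out)[1L] <- time_col
  out
}

#' Resample a quaternion series by component-wise linear interpolation
#'
#' Components are interpolated on the hemisphere-continuous representation and
#' renormalized. For the small inter-sample rotations of 60 Hz human-movement
#' data this is indistinguishable from spherical interpolation.
#'
#' @param qs A [quat_series].
#' @param target_hz Target sampling rate in Hz.
#' @return A [quat_series] on the uniform grid.
#' @export
resample_quat_series <- function(qs, target_hz) {
  stopifnot(inherits(qs, "quat_series"))
  df <- data.frame(time = qs$time, w = qs$q[, 1], x = qs$q[, 2],
                   y = qs$q[, 3], z = qs$q[, 4])
  r <- resample_linear(df, target_hz)
  quat_series(r$time, as.matrix(r[, c("w", "x", "y", "z")]))
}

#' Integer-lag synchronization by normalized cross-correlation
#'
#' Finds the integer lag `k` within `±max_lag` samples that maximizes the
#' Pearson correlation between `a[i]` and `b[i + k]`; if `b` is a copy of `a`
#' delayed by `k` samples the returned lag is `k`. Ties are broken toward the
#' smallest `|lag|` (negative before positive at equal magnitude). Sub-sample
#' refinement is deliberately not attempted: the quality-control features are
#' segment averages, insensitive to sub-sample offsets.
#'
#' @param a,b Numeric vectors or [angle_series] objects at equal sampling
#'   rates.
#' @param max_lag Maximum lag magnitude to search, in samples.
#' @return Integer lag in samples.
#' @export
xcorr_sync <- function(a, b, max_lag = 50L) {
  if (inherits(a, "angle_series")) a <- a$angle
  if (inherits(b, "angle_series")) b <- b$angle
  a <- as.numeric(a); b <- as.numeric(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero-variance signal")
  }
  n <- min(length(a), length(b))
  max_lag <- min(as.integer(max_lag), n - 2L)
  lags <- seq.int(-max_lag, max_lag)
  lags <- lags[order(abs(lags), lags)]
  best_lag <- 0L
  best_r <- -Inf
  for (k in lags) {
    if (k >= 0) {
      ai <- a[seq_len(n - k)]
      bi <- b[seq_len(n - k) + k]
    } else {
      ai <- a[seq_len(n + k) - k]
      bi <- b[seq_len(n + k)]
    }
    if (stats::sd(ai) == 0 || stats::sd(bi) == 0) next
    r <- stats::cor(ai, bi)
    # candidates are visited in order of |lag|; require a real improvement so
    # floating-point ties resolve toward the smallest-magnitude lag
    if (r > best_r + 1e-12) {
      best_r <- r
      best_lag <- k
    }
  }
  as.integer(best_lag)
}

# Shift a series by an integer lag with edge replication: out[i] = x[i + lag],
# indices clamped to the valid range. Works on vectors and matrices (rows).
shift_by_lag <- function(x, lag) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  idx <- pmin(pmax(seq_len(n) + as.integer(lag), 1L), n)
  if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE]
}

validate_annotations <- function(annotations, n_samples = NULL) {
  req <- c("trial_id", "phase", "joint", "start", "end")
  if (!all(req %in% names(annotations))) {
    stop("annotations need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(annotations) == 0L) return(invisible(annotations))
  if (any(annotations$start >= annotations$end)) {
    stop("annotation error: start must be smaller than end")
  }
  if (any(annotations$start < 0)) stop("bounds error: negative start index")
  if (!is.null(n_samples) && any(annotations$end > n_samples)) {
    stop("bounds error: annotation extends past the end of the stream")
  }
  for (key in split(annotations, list(annotations$trial_id, annotations$joint), drop = TRUE)) {
    key <- key[order(key$start), ]
    if (nrow(key) > 1L && any(key$end[-nrow(key)] > key$start[-1L])) {
      stop("ordering error: overlapping phase annotations within a trial")
    }
  }
  invisible(annotations)
}

#' Slice a prepared trial into per-joint task-phase segments
#'
#' @param trial An `imu_trial` object (see [generate_trial] / [read_cohort]);
#'   all streams must share the trial's time base.
#' @param annotations Data frame with columns `trial_id`, `phase`, `joint`,
#'   `start`, `end`; indices are 0-based, half-open `[start, end)`, on the
#'   trial's current sampling grid.
#' @return List of `imu_segment` objects, one per annotation row, in input
#'   order. Each segment carries the raw, AHRS and reference slices of the
#'   joint's module pair plus `phase`, `joint` and `trial_id`.
#' @export
slice_segments <- function(trial, annotations) {
  stopifnot(inherits(trial, "imu_trial"))
  validate_annotations(annotations, n_samples = length(trial$time))
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    joint <- as.character(ann$joint)
    if (!joint %in% names(trial$joints)) stop("unknown joint: ", joint)
    jd <- trial$joints[[joint]]
    idx <- seq.int(ann$start + 1L, ann$end)
    prox <- trial$modules[[jd$prox]]
    dist <- trial$modules[[jd$dist]]
    seg <- list(
      trial_id = as.character(ann$trial_id),
      phase = as.character(ann$phase),
      joint = joint,
      time = trial$time[idx],
      raw_prox = prox$raw[idx, , drop = FALSE],
      raw_dist = dist$raw[idx, , drop = FALSE],
      ahrs_prox = quat_series_slice(prox$ahrs, idx),
      ahrs_dist = quat_series_slice(dist$ahrs, idx),
      ref_joint = quat_series_slice(jd$ref, idx)
    )
    out[[i]] <- structure(seg, class = "imu_segment")
  }
  out
}
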