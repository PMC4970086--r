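# Segment features fed to the quality-control classifier, and their
# normalization. Sixteen features per joint-segment, computed from the raw
# accelerometer, gyroscope and magnetometer signals of the two modules
# spanning the joint:
#
#   f1,  f2   mean magnetic-field deviation from the reference value, per module
#   f3,  f4   variance of the magnetic-field magnitude, per module
#   f5,  f6   mean acceleration magnitude, per module (g)
#   f7,  f8   mean angular-velocity magnitude, per module (deg/s)
#   f9..f11   proportion of angular velocity per axis, module 1
#   f12..f14  proportion of angular velocity per axis, module 2
#   f15       difference between the two modules' mean magnetic field
#   f16       the same difference computed on the previous sequence
#
# "Magnetic field" of a module is summarized by the Euclidean norm of its
# 3-axis magnetometer signal: the norm is invariant to module orientation, so
# it characterizes the environment rather than the motion.

feature_names <- function() paste0("f", 1:16)

mag_norm <- function(raw) sqrt(raw$mx^2 + raw$my^2 + raw$mz^2)
accel_norm <- function(raw) sqrt(raw$ax^2 + raw$ay^2 + raw$az^2)
gyro_norm <- function(raw) sqrt(raw$gx^2 + raw$gy^2 + raw$gz^2)

pop_var <- function(x) mean((x - mean(x))^2)

axis_proportions <- function(raw) {
  m <- c(mean(abs(raw$gx)), mean(abs(raw$gy)), mean(abs(raw$gz)))
  s <- sum(m)
  # a segment with no rotation at all carries no direction information
  if (s <= 0) rep(1 / 3, 3L) else m / s
}

#' Extract the 16 quality-control features of a joint-segment
#'
#' @param segment An `imu_segment` (see [slice_segments]) carrying the raw
#'   signals of the proximal (module 1) and distal (module 2) modules.
#' @param previous The preceding `imu_segment` of the same joint within the
#'   trial, or `NULL` for the first phase. The inter-module field difference
#'   of the previous sequence (f16) captures the recent magnetic history; when
#'   absent it falls back to the current segment's value (f16 = f15) and the
#'   result is flagged with attribute `f16_imputed`.
#' @param mag_reference Calibration-time magnetic-field magnitude, in the same
#'   normalized field units as the magnetometer channels.
#' @return Named numeric vector `f1` .. `f16`.
#' @export
extract_features <- function(segment, previous = NULL, mag_reference = 1) {
  stopifnot(inherits(segment, "imu_segment"), mag_reference > 0)
  if (nrow(segment$raw_prox) == 0L) stop("empty segment")
  m1 <- mag_norm(segment$raw_prox)
  m2 <- mag_norm(segment$raw_dist)
  f15 <- mean(m1) - mean(m2)
  f16 <- if (is.null(previous)) f15 else {
    mean(mag_norm(previous$raw_prox)) - mean(mag_norm(previous$raw_dist))
  }
  v <- c(
    mean(m1) - mag_reference,
    mean(m2) - mag_reference,
    pop_var(m1),
    pop_var(m2),
    mean(accel_norm(segment$raw_prox)),
    mean(accel_norm(segment$raw_dist)),
    mean(gyro_norm(segment$raw_prox)),
    mean(gyro_norm(segment$raw_dist)),
    axis_proportions(segment$raw_prox),
    axis_proportions(segment$raw_dist),
    f15,
    f16
  )
  names(v) <- feature_names()
  attr(v, "f16_imputed") <- is.null(previous)
  v
}

signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

#' Fit the feature normalization model
#'
#' Features are compressed with a signed square root (`sign(x) * sqrt(|x|)`;
#' the plain square root is undefined for the signed field-difference
#' features) and standardized to z-scores with the mean and standard deviation
#' of the transformed training values. The model must be fitted on the
#' training partition only and reused unchanged on validation data.
#'
#' @param training Matrix or data frame of raw feature vectors (rows =
#'   segments, columns = features), at least two rows.
#' @return Object of class `qc_normalizer` with per-feature `mean`, `sd` and
#'   the clipping bound `clip_sd`.
#' @export
fit_normalizer <- function(training) {
  x <- as.matrix(training)
  if (nrow(x) < 2L) stop("need at least 2 training vectors")
  tx <- signed_sqrt(x)
  mu <- colMeans(tx)
  sdv <- apply(tx, 2L, stats::sd)
  if (any(sdv < 1e-12)) {
    bad <- colnames(x)[sdv < 1e-12]
    if (is.null(bad)) bad <- which(sdv < 1e-12)
    stop("degenerate feature (zero variance): ", paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdv, clip_sd = 3), class = "qc_normalizer")
}

#' Apply a fitted normalizer to feature vectors
#'
#' Transforms with the signed square root, standardizes with the training
#' statistics, and clips z-scores beyond `±clip_sd` standard deviations back
#' to the limit (outlier containment).
#'
#' @param model A `qc_normalizer` from [fit_normalizer].
#' @param v A single feature vector or a matrix/data frame of rows.
#' @return Normalized features in `[-clip_sd, clip_sd]`, same shape as `v`.
#' @export
apply_normalizer <- function(model, v) {
  if (!inherits(model, "qc_normalizer")) stop("model is not a fitted qc_normalizer")
  single <- is.null(dim(v))
  x <- if (single) matrix(as.numeric(v), nrow = 1L) else as.matrix(v)
  if (ncol(x) != length(model$mean)) stop("feature count does not match the model")
  z <- sweep(sweep(signed_sqrt(x), 2L, model$mean), 2L, model$sd, "/")
  z <- pmin(pmax(z, -model$clip_sd), model$clip_sd)
  if (single) {
    z <- drop(z)
    names(z) <- names(model$mean)
  }
  z
}
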