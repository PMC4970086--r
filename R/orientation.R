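# Joint orientation, global angular motion, RMSD and quality labels.

#' Relative orientation between two module orientation series
#'
#' Joint orientation is the orientation of the distal module expressed in the
#' frame of the proximal module: `q_rel = conj(q_prox) * q_dist` at each
#' sample. Both series must share timestamps; hemisphere continuity of the
#' result is enforced.
#'
#' @param proximal,distal Objects of class [quat_series] on identical
#'   timestamps (proximal and distal body segments of the joint).
#' @return A [quat_series] of joint orientations.
#' @export
relative_orientation_series <- function(proximal, distal) {
  stopifnot(inherits(proximal, "quat_series"), inherits(distal, "quat_series"))
  if (!same_timestamps(proximal, distal)) {
    stop("alignment error: proximal and distal series have different timestamps")
  }
  rel <- quat_multiply(quat_conjugate(proximal$q), distal$q)
  quat_series(proximal$time, rel)
}

#' Express a relative-orientation series against its initial sample
#'
#' Joint motion is referenced to the configuration at segment start:
#' `conj(q_rel[1]) * q_rel[t]`, so the first sample becomes the identity and
#' any constant mounting offset between the two modules cancels.
#'
#' @param rel A [quat_series] of relative orientations.
#' @return A [quat_series] starting at the identity quaternion.
#' @export
express_relative_to_initial <- function(rel) {
  stopifnot(inherits(rel, "quat_series"))
  if (length(rel$time) == 0L) stop("empty series")
  q0 <- rel$q[1L, ]
  quat_series(rel$time, quat_multiply(quat_conjugate(q0), rel$q))
}

#' Global angular motion of a joint
#'
#' The scalar rotation angle of the joint away from its initial configuration,
#' independent of the rotation axis: `theta(t) = 2 * acos(|w(t)|)` in degrees,
#' where `w` is the scalar part of the relative orientation referenced to the
#' initial sample. Using `|w|` makes the angle invariant to the quaternion
#' sign ambiguity; the acos argument is clamped to `[0, 1]` to absorb
#' floating-point overshoot.
#'
#' @param rel0 A [quat_series] already expressed relative to its initial
#'   sample (see [express_relative_to_initial]).
#' @return An [angle_series] with `angle[1] == 0`.
#' @export
global_motion_angle <- function(rel0) {
  stopifnot(inherits(rel0, "quat_series"))
  theta <- 2 * acos(pmin(abs(rel0$q[, 1]), 1)) * 180 / pi
  angle_series(rel0$time, theta)
}

#' Root-mean-squared difference between two angle series
#'
#' @param est,ref [angle_series] objects on identical timestamps (typically
#'   the AHRS-derived and gold-standard global motion of one segment).
#' @return RMSD in degrees.
#' @export
rmsd_deg <- function(est, ref) {
  stopifnot(inherits(est, "angle_series"), inherits(ref, "angle_series"))
  if (length(est$time) != length(ref$time) ||
      max(abs(est$time - ref$time)) > 1e-8) {
    stop("alignment error: angle series have different timestamps")
  }
  sqrt(mean((est$angle - ref$angle)^2))
}

#' Quality category from segment RMSD
#'
#' Segments are `good` when RMSD from the gold standard is at most 5 degrees
#' (within widely accepted error bounds for clinical kinematics), `bad` when
#' above 10 degrees (accuracy may alter the conclusions drawn), and
#' `tolerable` in between (usable with care, e.g. for task segmentation).
#' The boundaries belong to the lower category: 5 is good, 10 is tolerable.
#'
#' @param rmsd Non-negative RMSD value(s) in degrees.
#' @return Factor with levels `good`, `tolerable`, `bad`.
#' @export
label_from_rmsd <- function(rmsd) {
  rmsd <- as.numeric(rmsd)
  if (any(is.na(rmsd)) || any(rmsd < 0)) stop("rmsd must be non-negative")
  cut(rmsd, breaks = c(-Inf, 5, 10, Inf), labels = c("good", "tolerable", "bad"),
      right = TRUE)
}
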