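# Quaternion algebra for orientation series.
#
# Convention used throughout the package: scalar-first components (w, x, y, z),
# Hamilton product, right-handed frames. A single quaternion is a numeric
# vector of length 4; a batch is an n x 4 matrix with one quaternion per row.

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) {
    if (length(q) != 4L) stop("a quaternion has exactly 4 components (w, x, y, z)")
    q <- matrix(as.numeric(q), nrow = 1L)
  } else {
    q <- as.matrix(q)
    if (ncol(q) != 4L) stop("quaternion matrices must have 4 columns (w, x, y, z)")
    storage.mode(q) <- "double"
  }
  dimnames(q) <- list(NULL, c("w", "x", "y", "z"))
  q
}

# Restore vector shape when the caller passed a single quaternion.
restore_quat_shape <- function(out, template) {
  if (is.null(dim(template)) && nrow(out) == 1L) unname(drop(out)) else out
}

#' Normalize quaternions to unit norm
#'
#' @param q A length-4 numeric vector or an n x 4 matrix, scalar-first.
#' @return Input rescaled to unit norm, same shape as `q`.
#' @export
quat_normalize <- function(q) {
  qm <- as_quat_matrix(q)
  n <- sqrt(rowSums(qm^2))
  if (any(n < 1e-12)) stop("invalid quaternion: zero norm")
  restore_quat_shape(qm / n, q)
}

#' Quaternion conjugate
#'
#' @inheritParams quat_normalize
#' @return Conjugate (vector part negated), same shape as `q`.
#' @export
quat_conjugate <- function(q) {
  qm <- as_quat_matrix(q)
  qm[, 2:4] <- -qm[, 2:4]
  restore_quat_shape(qm, q)
}

#' Hamilton product of unit quaternions
#'
#' Row-wise product of two quaternion batches (either argument may be a single
#' quaternion, which is recycled). The result is renormalized so that chains of
#' products do not accumulate norm drift.
#'
#' @param a,b Length-4 vectors or n x 4 matrices, scalar-first, unit norm.
#' @return The product `a` \%*\% `b` (rotation `b` followed by `a` when
#'   quaternions map body to world coordinates), unit norm.
#' @export
quat_multiply <- function(a, b) {
  am <- as_quat_matrix(a)
  bm <- as_quat_matrix(b)
  if (nrow(am) == 1L && nrow(bm) > 1L) am <- am[rep.int(1L, nrow(bm)), , drop = FALSE]
  if (nrow(bm) == 1L && nrow(am) > 1L) bm <- bm[rep.int(1L, nrow(am)), , drop = FALSE]
  if (nrow(am) != nrow(bm)) stop("quaternion batches must have matching lengths")
  if (any(rowSums(am^2) < 1e-18) || any(rowSums(bm^2) < 1e-18)) {
    stop("invalid quaternion: zero norm")
  }
  out <- cbind(
    w = am[, 1] * bm[, 1] - am[, 2] * bm[, 2] - am[, 3] * bm[, 3] - am[, 4] * bm[, 4],
    x = am[, 1] * bm[, 2] + am[, 2] * bm[, 1] + am[, 3] * bm[, 4] - am[, 4] * bm[, 3],
    y = am[, 1] * bm[, 3] - am[, 2] * bm[, 4] + am[, 3] * bm[, 1] + am[, 4] * bm[, 2],
    z = am[, 1] * bm[, 4] + am[, 2] * bm[, 3] - am[, 3] * bm[, 2] + am[, 4] * bm[, 1]
  )
  out <- out / sqrt(rowSums(out^2))
  template <- if (is.null(dim(a)) && is.null(dim(b))) numeric(4) else matrix(0, 2, 4)
  restore_quat_shape(out, template)
}

#' Quaternion from axis and angle
#'
#' @param axis Length-3 rotation axis (need not be unit length).
#' @param angle_deg Rotation angle(s) in degrees; may be a vector, producing a
#'   batch of quaternions about the common axis.
#' @return Unit quaternion (or n x 4 matrix for vector `angle_deg`).
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  if (length(axis) != 3L) stop("axis must have 3 components")
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  axis <- axis / n
  half <- angle_deg * pi / 360
  out <- cbind(w = cos(half), x = axis[1] * sin(half),
               y = axis[2] * sin(half), z = axis[3] * sin(half))
  if (length(angle_deg) == 1L) unname(drop(out)) else out
}

# Quaternion exponential of a rotation vector (body rates integrated over dt):
# rotvec in degrees, rows are (rx, ry, rz). Vectorized.
quat_from_rotvec <- function(rotvec) {
  rv <- rotvec * pi / 180
  if (is.null(dim(rv))) rv <- matrix(rv, nrow = 1L)
  ang <- sqrt(rowSums(rv^2))
  half <- ang / 2
  # sinc(half) handles the zero-rotation limit without division by zero
  k <- ifelse(ang < 1e-12, 0.5, sin(half) / ang)
  out <- cbind(w = cos(half), x = rv[, 1] * k, y = rv[, 2] * k, z = rv[, 3] * k)
  if (is.null(dim(rotvec))) unname(drop(out)) else out
}

#' Rotation matrix of a unit quaternion
#'
#' @param q Length-4 unit quaternion, scalar-first.
#' @return 3 x 3 rotation matrix mapping body to world coordinates.
#' @export
quat_to_rotmat <- function(q) {
  q <- quat_normalize(as.numeric(q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Rotate 3-vectors by unit quaternions
#'
#' @param q Unit quaternion(s), length-4 vector or n x 4 matrix.
#' @param v 3-vector or n x 3 matrix of vectors (rows paired with rows of `q`).
#' @return Rotated vectors, same shape as `v` broadcast against `q`.
#' @export
quat_rotate_vector <- function(q, v) {
  qm <- as_quat_matrix(q)
  vm <- if (is.null(dim(v))) matrix(as.numeric(v), nrow = 1L) else as.matrix(v)
  if (ncol(vm) != 3L) stop("vectors must have 3 components")
  n <- max(nrow(qm), nrow(vm))
  if (nrow(qm) == 1L) qm <- qm[rep.int(1L, n), , drop = FALSE]
  if (nrow(vm) == 1L) vm <- vm[rep.int(1L, n), , drop = FALSE]
  if (nrow(qm) != nrow(vm)) stop("quaternion and vector batches must match")
  w <- qm[, 1]; u <- qm[, 2:4, drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  cross <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  t1 <- cross(u, vm)
  out <- vm + 2 * w * t1 + 2 * cross(u, t1)
  if (is.null(dim(v)) && nrow(out) == 1L) drop(out) else out
}

#' Enforce hemisphere continuity of a quaternion sequence
#'
#' Unit quaternions double-cover rotations: q and -q represent the same
#' rotation. Sign flips between consecutive samples produce spurious jumps in
#' derived angles, so each quaternion is flipped, if needed, to keep the dot
#' product with its predecessor non-negative. The represented rotations are
#' unchanged.
#'
#' @param q n x 4 matrix of unit quaternions.
#' @return Matrix with consecutive dot products >= 0.
#' @export
quat_enforce_continuity <- function(q) {
  qm <- as_quat_matrix(q)
  if (nrow(qm) < 2L) return(restore_quat_shape(qm, q))
  d <- rowSums(qm[-1L, , drop = FALSE] * qm[-nrow(qm), , drop = FALSE])
  s <- cumprod(ifelse(d < 0, -1, 1))
  qm[-1L, ] <- qm[-1L, , drop = FALSE] * s
  restore_quat_shape(qm, q)
}

#' Construct a time-stamped quaternion series
#'
#' @param time Strictly increasing numeric timestamps in seconds.
#' @param q n x 4 matrix of scalar-first quaternions (normalized on input;
#'   hemisphere continuity is enforced).
#' @return Object of class `quat_series` with fields `time` and `q`.
#' @export
quat_series <- function(time, q) {
  time <- as.numeric(time)
  qm <- as_quat_matrix(q)
  if (length(time) != nrow(qm)) stop("time and quaternion lengths differ")
  if (length(time) == 0L) stop("empty quaternion series")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  qm <- quat_enforce_continuity(as_quat_matrix(quat_normalize(qm)))
  structure(list(time = time, q = qm), class = "quat_series")
}

#' @export
print.quat_series <- function(x, ...) {
  cat(sprintf("<quat_series> %d samples, %.2f s to %.2f s\n",
              length(x$time), x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' @export
length.quat_series <- function(x) length(x$time)

# Subset a quat_series by sample indices (internal).
quat_series_slice <- function(qs, idx) {
  structure(list(time = qs$time[idx], q = qs$q[idx, , drop = FALSE]),
            class = "quat_series")
}

#' Construct a time-stamped scalar angle series
#'
#' @param time Strictly increasing numeric timestamps in seconds.
#' @param angle Angles in degrees, same length as `time`.
#' @return Object of class `angle_series` with fields `time` and `angle`.
#' @export
angle_series <- function(time, angle) {
  time <- as.numeric(time)
  angle <- as.numeric(angle)
  if (length(time) != length(angle)) stop("time and angle lengths differ")
  if (length(time) == 0L) stop("empty angle series")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(time = time, angle = angle), class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d samples, range %.2f deg to %.2f deg\n",
              length(x$time), min(x$angle), max(x$angle)))
  invisible(x)
}

same_timestamps <- function(a, b, tol = 1e-8) {
  length(a$time) == length(b$time) && max(abs(a$time - b$time)) <= tol
}
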