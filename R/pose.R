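# Column schema shared by all sample streams.
SAMPLE_COLUMNS <- c("t", "sensor_id", "x", "y", "z", "qw", "qx", "qy", "qz")

# Quaternions are accepted when within this tolerance of unit norm and
# renormalized; beyond it they are rejected as invalid orientations.
# 1e-6 accommodates values round-tripped through text at 6 significant digits.
QUAT_NORM_TOL <- 1e-6

# Tracker working volume is a cube 75 cm per side; coordinates beyond this
# trigger a soft warning, never an error.
WORKING_VOLUME_HALF_MM <- 750

#' Build a pose-sample data frame
#'
#' A pose sample is one time-stamped six-degree-of-freedom reading from one
#' sensor: position in millimetres in the base-station frame plus a
#' scalar-first unit quaternion (w, x, y, z) rotating sensor-local axes into
#' base-station axes.
#'
#' @param t numeric vector of timestamps in seconds.
#' @param sensor_id integer vector of sensor labels.
#' @param position numeric matrix with one row per sample and columns x, y, z
#'   in millimetres.
#' @param quaternion numeric matrix with one row per sample and columns
#'   qw, qx, qy, qz; defaults to the identity orientation.
#' @return A data frame with columns `t`, `sensor_id`, `x`, `y`, `z`, `qw`,
#'   `qx`, `qy`, `qz`, validated and with quaternions renormalized to unit
#'   length.
#' @examples
#' pose_samples(t = 0, sensor_id = 1L, position = rbind(c(10, 20, 30)))
#' @export
pose_samples <- function(t, sensor_id, position, quaternion = NULL) {
  position <- rbind(position)
  n <- length(t)
  stopifnot(nrow(position) == n, ncol(position) == 3)
  if (is.null(quaternion)) {
    quaternion <- cbind(rep(1, n), 0, 0, 0)
  }
  quaternion <- rbind(quaternion)
  stopifnot(nrow(quaternion) == n, ncol(quaternion) == 4)
  df <- data.frame(
    t = as.numeric(t), sensor_id = as.integer(sensor_id),
    x = position[, 1], y = position[, 2], z = position[, 3],
    qw = quaternion[, 1], qx = quaternion[, 2],
    qy = quaternion[, 3], qz = quaternion[, 4]
  )
  validate_samples(df)
}

#' Validate a sample stream
#'
#' Checks the column schema, finiteness, quaternion norms (renormalizing
#' within tolerance) and warns when coordinates leave the tracker working
#' volume (a cube 75 cm per side).
#'
#' @param samples data frame with the pose-sample columns.
#' @return The validated data frame (quaternions renormalized).
#' @export
validate_samples <- function(samples) {
  missing <- setdiff(SAMPLE_COLUMNS, names(samples))
  if (length(missing) > 0) {
    stop("sample stream is missing column(s): ", paste(missing, collapse = ", "))
  }
  num <- as.matrix(samples[, c("x", "y", "z", "qw", "qx", "qy", "qz")])
  if (!all(is.finite(num)) || !all(is.finite(samples$t))) {
    stop("sample stream contains non-finite values")
  }
  nrm <- sqrt(samples$qw^2 + samples$qx^2 + samples$qy^2 + samples$qz^2)
  if (any(abs(nrm - 1) > QUAT_NORM_TOL)) {
    stop("invalid orientation: quaternion norm deviates from 1 by more than ",
         format(QUAT_NORM_TOL))
  }
  samples$qw <- samples$qw / nrm
  samples$qx <- samples$qx / nrm
  samples$qy <- samples$qy / nrm
  samples$qz <- samples$qz / nrm
  if (any(abs(samples[, c("x", "y", "z")]) > WORKING_VOLUME_HALF_MM)) {
    warning("some coordinates exceed the 750 mm tracker working half-volume")
  }
  samples
}

#' Convert unit quaternions to rotation matrices
#'
#' @param q numeric vector of length 4 (w, x, y, z) or a matrix with one
#'   quaternion per row.
#' @return A 3x3 rotation matrix, or a list of matrices for matrix input.
#' @export
quat_to_matrix <- function(q) {
  if (is.matrix(q) && nrow(q) > 1) {
    return(lapply(seq_len(nrow(q)), function(i) quat_to_matrix(q[i, ])))
  }
  q <- as.numeric(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Rotate row-vectors v (n x 3) by per-row quaternions q (n x 4), i.e. R %*% v.
# Uses v' = v + 2 qv x (qv x v + w v), fully vectorized.
quat_rotate_rows <- function(q, v) {
  w <- q[, 1]
  qv <- q[, 2:4, drop = FALSE]
  cross_rows <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  t1 <- cross_rows(qv, v) + w * v
  v + 2 * cross_rows(qv, t1)
}

#' Match each sample to the nearest-in-time reference pose
#'
#' Sample streams from the glove and the object-mounted reference sensor are
#' asynchronous; each glove sample is paired with the reference pose closest
#' in time, ties broken toward the earlier reference sample, and times beyond
#' the reference stream clamp to its extremes.
#'
#' @param t numeric vector of query timestamps (seconds).
#' @param ref_stream reference-sensor sample data frame, time-sorted.
#' @return Integer vector of row indices into `ref_stream`.
#' @export
match_reference_pose <- function(t, ref_stream) {
  if (is.null(ref_stream) || nrow(ref_stream) == 0) {
    stop("no reference stream: cannot match reference poses")
  }
  rt <- ref_stream$t
  if (is.unsorted(rt)) stop("reference stream must be time-sorted")
  idx <- findInterval(t, rt)
  idx[idx == 0L] <- 1L
  has_next <- idx < length(rt)
  nxt <- pmin(idx + 1L, length(rt))
  # strictly closer later sample wins; ties stay with the earlier one
  take_next <- has_next & (rt[nxt] - t) < (t - rt[idx])
  idx[take_next] <- nxt[take_next]
  idx
}

#' Re-express glove samples in the object (reference-sensor) frame
#'
#' Each glove sample is translated and rotated into the frame of the
#' object-mounted reference sensor: `p_obj = R_ref' (p - p_ref)` where
#' `R_ref` and `p_ref` are the orientation and position of the reference
#' pose matched nearest in time. If the object moves rigidly during the
#' scan and the reference sensor moves with it, the resulting object-frame
#' cloud is identical to the one from a static scene, so the image is not
#' distorted by object motion.
#'
#' @param samples glove sample data frame (pose-sample schema).
#' @param ref_stream reference-sensor sample data frame, time-sorted. May
#'   also be a single reference pose (one-row data frame).
#' @return Data frame with columns `x`, `y`, `z` (object frame, mm),
#'   `sensor_id`, `t`.
#' @export
to_object_frame <- function(samples, ref_stream) {
  samples <- validate_samples(samples)
  ref_stream <- validate_samples(ref_stream)
  idx <- match_reference_pose(samples$t, ref_stream)
  p <- as.matrix(samples[, c("x", "y", "z")])
  pref <- as.matrix(ref_stream[idx, c("x", "y", "z"), drop = FALSE])
  qref <- as.matrix(ref_stream[idx, c("qw", "qx", "qy", "qz"), drop = FALSE])
  # R' v == rotation by the conjugate quaternion
  qconj <- cbind(qref[, 1], -qref[, 2:4, drop = FALSE])
  obj <- quat_rotate_rows(qconj, p - pref)
  data.frame(x = obj[, 1], y = obj[, 2], z = obj[, 3],
             sensor_id = samples$sensor_id, t = samples$t)
}

#' Cartesian to spherical coordinates about an origin
#'
#' Azimuth is measured in the x-y plane from +x toward +y, in degrees in
#' \[0, 360); elevation from the x-y plane toward +z, in \[-90, +90\].
#' Points on the polar axis get azimuth 0 by convention.
#'
#' @param p numeric matrix of points (one per row, mm) or a 3-vector.
#' @param origin numeric 3-vector, the reference point acting as origin.
#' @return Data frame with columns `r` (mm), `az`, `el` (degrees).
#' @export
cart_to_spherical <- function(p, origin = c(0, 0, 0)) {
  p <- rbind(p)
  d <- sweep(p, 2, as.numeric(origin))
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("degenerate direction: point coincides with origin")
  az <- atan2(d[, 2], d[, 1]) * 180 / pi
  az <- az %% 360
  el <- asin(pmin(1, pmax(-1, d[, 3] / r))) * 180 / pi
  data.frame(r = r, az = az, el = el)
}

#' Spherical to Cartesian coordinates (inverse of [cart_to_spherical()])
#'
#' @param r radius in mm (non-negative).
#' @param az azimuth in degrees.
#' @param el elevation in degrees.
#' @param origin numeric 3-vector added to the result.
#' @return Numeric matrix of points, one per row.
#' @export
spherical_to_cart <- function(r, az, el, origin = c(0, 0, 0)) {
  azr <- az * pi / 180
  elr <- el * pi / 180
  p <- cbind(r * cos(elr) * cos(azr),
             r * cos(elr) * sin(azr),
             r * sin(elr))
  sweep(p, 2, as.numeric(origin), `+`)
}
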