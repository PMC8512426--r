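# Synthetic glove scanning sessions: stands in for the tracker hardware.

#' Rigid object motion
#'
#' Time-parameterized rigid motion of the scanned object (and of the
#' reference sensor mounted on it): rotation at a constant angular rate
#' about an axis through a pivot, plus a constant translation velocity.
#' The motion is the identity at t = 0.
#'
#' @param axis rotation axis (3-vector, need not be unit).
#' @param rate_deg_s angular rate in degrees per second.
#' @param velocity translation velocity in mm per second (3-vector).
#' @param pivot point the rotation axis passes through (mm).
#' @return An object of class `rigid_motion`.
#' @export
rigid_motion <- function(axis = c(0, 0, 1), rate_deg_s = 0,
                         velocity = c(0, 0, 0), pivot = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("rotation axis must be non-zero")
  structure(list(axis = axis / nrm, rate_deg_s = rate_deg_s,
                 velocity = as.numeric(velocity), pivot = as.numeric(pivot)),
            class = "rigid_motion")
}

#' Rotation quaternion of a rigid motion at given times
#'
#' @param motion a [rigid_motion()].
#' @param t numeric vector of times in seconds.
#' @return Matrix of scalar-first quaternions (w, x, y, z), one row per time.
#' @export
motion_quaternion <- function(motion, t) {
  ang <- motion$rate_deg_s * t * pi / 180
  cbind(cos(ang / 2),
        sin(ang / 2) * motion$axis[1],
        sin(ang / 2) * motion$axis[2],
        sin(ang / 2) * motion$axis[3])
}

#' Apply a rigid motion to static-scene points
#'
#' @param motion a [rigid_motion()].
#' @param p numeric matrix of points (one per row, mm).
#' @param t numeric vector of per-point times in seconds.
#' @return Matrix of moved points.
#' @export
apply_motion <- function(motion, p, t) {
  p <- rbind(p)
  q <- motion_quaternion(motion, t)
  moved <- quat_rotate_rows(q, sweep(p, 2, motion$pivot))
  moved <- sweep(moved, 2, motion$pivot, `+`)
  moved + outer(t, motion$velocity)
}

#' Trace generator configuration
#'
#' Models the statistics of a clinician repeatedly stroking a hand over
#' the object: a fraction of samples are on-surface contact points, a
#' fraction are transit points recorded while the hand moves through air
#' (lifted off the surface along the local normal), and a small rate of
#' gross outliers emulates occasional tracker glitches. Sensor noise is
#' isotropic Gaussian; the default per-axis sigma makes the 3-D RMS
#' position error equal the tracker specification of 1.4 mm.
#'
#' @param n_samples number of glove samples to emit.
#' @param fraction_transit fraction of samples recorded off-surface.
#' @param lift_range range (mm) of the uniform off-surface lift distance.
#' @param noise_sigma per-axis Gaussian noise sigma in mm
#'   (default `1.4 / sqrt(3)` so the 3-D RMS error is 1.4 mm).
#' @param gross_outlier_rate fraction of samples displaced by a gross error.
#' @param gross_outlier_magnitude displacement of gross outliers in mm.
#' @param seed RNG seed; mandatory so traces are reproducible.
#' @param n_glove_sensors number of glove-mounted sensors whose ids
#'   interleave in the stream (default 3: thumb, forefinger, middle finger).
#' @param sample_rate_hz sampling rate used to build timestamps.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(n_samples = 10000, fraction_transit = 0.5,
                         lift_range = c(10, 100),
                         noise_sigma = 1.4 / sqrt(3),
                         gross_outlier_rate = 0.01,
                         gross_outlier_magnitude = 300,
                         seed, n_glove_sensors = 3, sample_rate_hz = 100) {
  if (missing(seed)) stop("a seed is required for reproducible traces")
  stopifnot(n_samples >= 1,
            fraction_transit >= 0, fraction_transit <= 1,
            noise_sigma >= 0,
            gross_outlier_rate >= 0, gross_outlier_rate <= 1,
            fraction_transit + gross_outlier_rate <= 1,
            length(lift_range) == 2, lift_range[1] <= lift_range[2],
            n_glove_sensors >= 1, sample_rate_hz > 0)
  structure(list(n_samples = as.integer(n_samples),
                 fraction_transit = fraction_transit,
                 lift_range = lift_range, noise_sigma = noise_sigma,
                 gross_outlier_rate = gross_outlier_rate,
                 gross_outlier_magnitude = gross_outlier_magnitude,
                 seed = as.integer(seed),
                 n_glove_sensors = as.integer(n_glove_sensors),
                 sample_rate_hz = sample_rate_hz),
            class = "trace_config")
}

# Run expr with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a glove scanning trace over a surface model
#'
#' Emits a labelled stream of glove pose samples plus the synchronized
#' stream of the object-mounted reference sensor. Surface samples are
#' exact surface points plus sensor noise; transit samples are surface
#' points displaced outward along the local normal by a uniform lift;
#' gross outliers are displaced by a fixed magnitude in a random
#' direction. Noise is drawn in the static object frame and carried
#' through any rigid motion, so motion compensation can be tested as an
#' exact identity. Deterministic given the seed in `cfg`.
#'
#' @param model a `surface_model`.
#' @param cfg a [trace_config()].
#' @param motion optional [rigid_motion()] applied to the object and its
#'   reference sensor during the scan.
#' @param reference_sensor_id sensor id of the object-mounted sensor
#'   (default 0).
#' @return An object of class `glove_trace`: list with `samples` (glove
#'   pose-sample data frame), `ref_stream` (reference-sensor pose stream at
#'   the same timestamps), `labels` (character: surface / transit /
#'   gross_outlier per glove sample), and `static_points` (the noise-free
#'   plus noise object-frame positions before motion, for evaluation).
#' @export
generate_trace <- function(model, cfg, motion = NULL,
                           reference_sensor_id = 0L) {
  stopifnot(inherits(model, "surface_model"), inherits(cfg, "trace_config"))
  n <- cfg$n_samples
  with_seed(cfg$seed, {
    smp <- surface_sample(model, n)
    u <- stats::runif(n)
    labels <- rep("surface", n)
    labels[u < cfg$fraction_transit] <- "transit"
    labels[u >= cfg$fraction_transit &
             u < cfg$fraction_transit + cfg$gross_outlier_rate] <- "gross_outlier"
    pts <- smp$points
    tr <- labels == "transit"
    if (any(tr)) {
      # the hand lifts off from locations it touched: each transit sample is
      # a normal-offset copy of one of the emitted contact points (falling
      # back to its own base point when no surface samples exist)
      surf_idx <- which(labels == "surface")
      foot <- if (length(surf_idx) > 0) {
        surf_idx[sample.int(length(surf_idx), sum(tr), replace = TRUE)]
      } else {
        which(tr)
      }
      lift <- stats::runif(sum(tr), cfg$lift_range[1], cfg$lift_range[2])
      pts[tr, ] <- smp$points[foot, , drop = FALSE] +
        smp$normals[foot, , drop = FALSE] * lift
    }
    go <- labels == "gross_outlier"
    if (any(go)) {
      dir <- matrix(stats::rnorm(3 * sum(go)), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      pts[go, ] <- pts[go, , drop = FALSE] + dir * cfg$gross_outlier_magnitude
    }
    if (cfg$noise_sigma > 0) {
      pts <- pts + matrix(stats::rnorm(3 * n, sd = cfg$noise_sigma), ncol = 3)
    }
    t <- (seq_len(n) - 1) / cfg$sample_rate_hz
    sensor_id <- ((seq_len(n) - 1) %% cfg$n_glove_sensors) + 1L

    # The object-mounted reference sensor reports the object's rigid pose;
    # its frame is taken to coincide with the model frame at t = 0 (a
    # calibration convention — where the sensor physically sits on the
    # object only shifts all object-frame coordinates by a constant).
    ref_pos0 <- c(0, 0, 0)
    if (is.null(motion)) {
      glove <- pts
      ref_pos <- matrix(ref_pos0, n, 3, byrow = TRUE)
      ref_q <- cbind(rep(1, n), 0, 0, 0)
    } else {
      glove <- apply_motion(motion, pts, t)
      ref_pos <- apply_motion(motion, matrix(ref_pos0, n, 3, byrow = TRUE), t)
      ref_q <- motion_quaternion(motion, t)
    }
    samples <- pose_samples(t, sensor_id, glove)
    ref_stream <- pose_samples(t, rep(as.integer(reference_sensor_id), n),
                               ref_pos, ref_q)
    structure(list(samples = samples, ref_stream = ref_stream,
                   labels = labels, static_points = pts,
                   model = model, cfg = cfg, motion = motion),
              class = "glove_trace")
  })
}

#' @export
print.glove_trace <- function(x, ...) {
  cat("Simulated glove trace:", nrow(x$samples), "samples over a",
      x$model$kind, "model\n")
  print(round(100 * table(x$labels) / length(x$labels), 2))
  if (!is.null(x$motion)) cat("  rigid object motion enabled\n")
  invisible(x)
}
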