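#' Solid-angular sector grid
#'
#' Partitions the directions around a reference point into an equal-angle
#' azimuth x elevation grid of the given angular size. Every direction maps
#' to exactly one sector; near-pole sectors subtend smaller solid angles
#' than equatorial ones, which is accepted for simplicity.
#'
#' @param angular_size sector edge in degrees, in (0, 90].
#' @return An object of class `sector_grid` with fields `angular_size`,
#'   `n_az`, `n_el`.
#' @export
sector_grid <- function(angular_size) {
  if (!is.numeric(angular_size) || length(angular_size) != 1 ||
      !is.finite(angular_size) || angular_size <= 0 || angular_size > 90) {
    stop("angular_size must be a single value in (0, 90] degrees")
  }
  structure(list(angular_size = angular_size,
                 n_az = ceiling(360 / angular_size),
                 n_el = ceiling(180 / angular_size)),
            class = "sector_grid")
}

#' Sector index of spherical coordinates
#'
#' @param az azimuth in degrees (vectorized).
#' @param el elevation in degrees in \[-90, 90\] (vectorized).
#' @param grid a [sector_grid()].
#' @return Data frame with integer columns `i_az` in \[0, n_az) and `i_el`
#'   in \[0, n_el): azimuth wraps (360 maps to 0) and the +90 pole clamps
#'   into the top elevation row.
#' @export
sector_index <- function(az, el, grid) {
  stopifnot(inherits(grid, "sector_grid"))
  d <- grid$angular_size
  i_az <- floor((az %% 360) / d)
  i_az <- pmin(i_az, grid$n_az - 1L)
  i_el <- floor((el + 90) / d)
  i_el <- pmax(0, pmin(i_el, grid$n_el - 1L))
  data.frame(i_az = as.integer(i_az), i_el = as.integer(i_el))
}

#' Filter configuration
#'
#' @param angular_size fine selection-grid sector size in degrees.
#' @param coarse_factor ratio of the outlier-rejection grid size to the
#'   selection grid size (>= 1); the coarse sector size is capped at 90
#'   degrees. Default 4 so that coarse sectors usually hold enough selected
#'   points for a meaningful mean.
#' @param outlier_threshold fraction above the coarse-sector mean radius at
#'   which a point is rejected; default 0.20 (a point more than 20% further
#'   away than the sector average is dropped).
#' @param min_sector_count minimum number of points a coarse sector needs
#'   before the outlier rule applies; smaller sectors pass through
#'   unchanged. Default 3.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(angular_size = 1, coarse_factor = 4,
                          outlier_threshold = 0.20, min_sector_count = 3) {
  if (outlier_threshold <= 0 || outlier_threshold >= 1) {
    stop("outlier_threshold must lie strictly between 0 and 1")
  }
  if (coarse_factor < 1) stop("coarse_factor must be >= 1")
  if (min_sector_count < 2) stop("min_sector_count must be >= 2")
  fine <- sector_grid(angular_size)
  coarse <- sector_grid(min(90, angular_size * coarse_factor))
  structure(list(angular_size = angular_size, coarse_factor = coarse_factor,
                 outlier_threshold = outlier_threshold,
                 min_sector_count = as.integer(min_sector_count),
                 fine_grid = fine, coarse_grid = coarse),
            class = "filter_config")
}

#' Reference points
#'
#' Builds the reference-point table used to anchor the sector filter. Each
#' reference point is an origin assumed to lie inside the scanned object.
#'
#' @param positions numeric matrix, one reference point per row (mm, object
#'   frame), or a 3-vector.
#' @param id optional integer ids (default consecutive from 1); must be
#'   unique.
#' @return Data frame with columns `id`, `x`, `y`, `z`.
#' @export
reference_points <- function(positions, id = NULL) {
  positions <- rbind(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  if (is.null(id)) id <- seq_len(nrow(positions))
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("reference point ids must be unique")
  data.frame(id = id, x = positions[, 1], y = positions[, 2], z = positions[, 3])
}

#' Assign each point to its nearest reference point
#'
#' Each reference point validates the data closest to it; assignment is by
#' minimal Euclidean distance, ties broken toward the lowest reference id.
#'
#' @param points data frame or matrix with columns/cols `x`, `y`, `z`.
#' @param refs reference-point data frame from [reference_points()].
#' @return Integer vector of reference ids, one per point.
#' @export
assign_to_nearest_reference <- function(points, refs) {
  if (is.null(refs) || nrow(refs) == 0) stop("at least one reference point is required")
  p <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  ord <- order(refs$id)
  refs <- refs[ord, , drop = FALSE]
  dmat <- vapply(seq_len(nrow(refs)), function(k) {
    (p[, 1] - refs$x[k])^2 + (p[, 2] - refs$y[k])^2 + (p[, 3] - refs$z[k])^2
  }, numeric(nrow(p)))
  dmat <- matrix(dmat, nrow = nrow(p))
  best <- max.col(-dmat, ties.method = "first")
  refs$id[best]
}

#' Selectivity: percentage of raw samples retained
#'
#' @param raw_count number of raw samples (> 0).
#' @param kept_count number of retained samples (0 <= kept <= raw).
#' @return Retained percentage, `100 * kept / raw`.
#' @export
selectivity <- function(raw_count, kept_count) {
  if (raw_count <= 0) stop("selectivity is undefined for an empty raw set")
  if (kept_count < 0 || kept_count > raw_count) {
    stop("kept_count must lie in [0, raw_count]")
  }
  100 * kept_count / raw_count
}

#' Compute a reference point from a time window of glove samples
#'
#' The reference point is the average location of all glove sensors
#' (excluding the object-mounted reference sensor) over a fixed period of
#' time; during that window the user holds the glove inside (e.g. wrapped
#' around) the object so the mean falls in the object's interior.
#'
#' @param samples object-frame sample data frame with columns `x`, `y`,
#'   `z`, `sensor_id`, `t`.
#' @param window numeric length-2 vector `c(t0, t1)` in seconds, inclusive.
#' @param reference_sensor_id sensor id of the object-mounted sensor to
#'   exclude (default 0).
#' @param id id for the resulting reference point (default 1).
#' @return A one-row [reference_points()] data frame.
#' @export
compute_reference_point <- function(samples, window,
                                    reference_sensor_id = 0L, id = 1L) {
  sel <- samples$t >= window[1] & samples$t <= window[2] &
    samples$sensor_id != reference_sensor_id
  if (!any(sel)) stop("no non-reference samples inside the window")
  reference_points(c(mean(samples$x[sel]), mean(samples$y[sel]),
                     mean(samples$z[sel])), id = id)
}

# Composite sector key (single integer-valued double) for grouping.
sector_key <- function(ref_id, idx, grid) {
  as.numeric(ref_id) * (grid$n_az * grid$n_el) +
    as.numeric(idx$i_el) * grid$n_az + as.numeric(idx$i_az)
}

#' Select the closest point per solid-angular sector
#'
#' The volume-minimization step: around each assigned reference point the
#' directions are binned into sectors of the fine grid and, within each
#' sector, only the point closest to the origin is retained — the retained
#' set encloses the reference point in the smallest volume, which is what
#' makes it track the object surface. Ties on radius break toward the
#' earliest timestamp, then the lowest sensor id.
#'
#' This is an internal stage of [filter_cloud()], exported for testing and
#' for building custom pipelines.
#'
#' @param points object-frame point data frame (`x`, `y`, `z`, `sensor_id`,
#'   `t`) already assigned to a single reference point.
#' @param origin numeric 3-vector, the reference point position.
#' @param grid a [sector_grid()].
#' @return Logical vector: TRUE for points selected as the sector minimum.
#'   Points coincident with the origin are skipped with a warning and
#'   never selected.
#' @export
select_closest_per_sector <- function(points, origin, grid) {
  n <- nrow(points)
  keep <- logical(n)
  if (n == 0) return(keep)
  p <- as.matrix(points[, c("x", "y", "z")])
  d <- sweep(p, 2, as.numeric(origin))
  r <- sqrt(rowSums(d^2))
  ok <- r > 0
  if (any(!ok)) warning(sum(!ok), " point(s) coincide with the reference point; skipped")
  if (!any(ok)) return(keep)
  sph <- cart_to_spherical(p[ok, , drop = FALSE], origin)
  idx <- sector_index(sph$az, sph$el, grid)
  key <- sector_key(0L, idx, grid)
  ord <- order(key, sph$r, points$t[ok], points$sensor_id[ok])
  first <- ord[!duplicated(key[ord])]
  keep_ok <- logical(sum(ok))
  keep_ok[first] <- TRUE
  keep[ok] <- keep_ok
  keep
}

#' Coarse-sector mean-relative outlier rejection
#'
#' Operates after the selection filter, at a coarser angular resolution so
#' that enough points are available to compute a stable average: within
#' each coarse sector holding at least `min_sector_count` points, the mean
#' radius (candidate included) is computed and every point more than
#' `threshold` (default 20%) further away than that average is eliminated.
#' Under-populated sectors pass through unchanged.
#'
#' @param points object-frame point data frame assigned to one reference.
#' @param origin numeric 3-vector, the reference point position.
#' @param coarse_grid a [sector_grid()] no finer than the selection grid.
#' @param threshold rejection fraction above the sector mean (> 0).
#' @param min_sector_count minimum sector occupancy for the rule to apply.
#' @return Logical vector: TRUE for points that survive.
#' @export
reject_outliers <- function(points, origin, coarse_grid, threshold = 0.20,
                            min_sector_count = 3) {
  if (threshold <= 0) stop("outlier threshold must be positive")
  n <- nrow(points)
  if (n == 0) return(logical(0))
  sph <- cart_to_spherical(as.matrix(points[, c("x", "y", "z")]), origin)
  idx <- sector_index(sph$az, sph$el, coarse_grid)
  key <- sector_key(0L, idx, coarse_grid)
  cnt <- ave(sph$r, key, FUN = length)
  rbar <- ave(sph$r, key, FUN = mean)
  cnt < min_sector_count | sph$r <= (1 + threshold) * rbar
}

#' Run the full validation filter over a raw object-frame cloud
#'
#' The core pipeline: every point is hard-assigned to its nearest reference
#' point; per reference, the fine-grid selection keeps only the closest
#' point per solid-angular sector; the surviving points then pass through
#' the coarse-grid mean-relative outlier rejector. The filter is stateless:
#' incremental scanning is supported by re-running it on the whole
#' accumulated raw buffer (see [scan_session()]), which is also how the
#' original acquisition pipeline behaves — old and new data are always
#' filtered together.
#'
#' @param points object-frame point data frame with columns `x`, `y`, `z`,
#'   `sensor_id`, `t` (e.g. from [to_object_frame()]).
#' @param refs reference-point data frame from [reference_points()].
#' @param config a [filter_config()].
#' @return An object of class `validated_cloud`: list with `points` (the
#'   input plus provenance columns `ref_id`, `i_az`, `i_el`, `r`, `status`),
#'   `refs`, `config`, and counts per stage. Status is one of `selected`,
#'   `dropped_not_closest`, `dropped_outlier`, or `dropped_degenerate` for
#'   points coincident with their reference point.
#' @export
filter_cloud <- function(points, refs, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (is.null(refs) || nrow(refs) == 0) stop("at least one reference point is required")
  points <- as.data.frame(points)
  if (nrow(points) == 0) {
    pts <- cbind(points[, intersect(c("x", "y", "z", "sensor_id", "t"), names(points)), drop = FALSE],
                 ref_id = integer(0), i_az = integer(0), i_el = integer(0),
                 r = numeric(0), status = character(0))
    return(new_validated_cloud(pts, refs, config, 0L, 0L, 0L))
  }
  if (!all(c("x", "y", "z") %in% names(points))) {
    stop("points must have columns x, y, z")
  }
  if (is.null(points$t)) points$t <- seq_len(nrow(points))
  if (is.null(points$sensor_id)) points$sensor_id <- 1L

  ref_id <- assign_to_nearest_reference(points, refs)
  n <- nrow(points)
  status <- rep("dropped_not_closest", n)
  i_az <- rep(NA_integer_, n)
  i_el <- rep(NA_integer_, n)
  r <- rep(NA_real_, n)

  for (k in seq_len(nrow(refs))) {
    rid <- refs$id[k]
    origin <- c(refs$x[k], refs$y[k], refs$z[k])
    in_ref <- which(ref_id == rid)
    if (length(in_ref) == 0) next
    sub <- points[in_ref, , drop = FALSE]
    d <- cbind(sub$x - origin[1], sub$y - origin[2], sub$z - origin[3])
    rr <- sqrt(rowSums(d^2))
    r[in_ref] <- rr
    degen <- rr == 0
    status[in_ref[degen]] <- "dropped_degenerate"
    keep <- select_closest_per_sector(sub, origin, config$fine_grid)
    idx_ok <- which(rr > 0)
    if (length(idx_ok) > 0) {
      sph <- cart_to_spherical(d[idx_ok, , drop = FALSE], c(0, 0, 0))
      si <- sector_index(sph$az, sph$el, config$fine_grid)
      i_az[in_ref[idx_ok]] <- si$i_az
      i_el[in_ref[idx_ok]] <- si$i_el
    }
    sel <- in_ref[keep]
    if (length(sel) > 0) {
      surv <- reject_outliers(points[sel, , drop = FALSE], origin,
                              config$coarse_grid, config$outlier_threshold,
                              config$min_sector_count)
      status[sel] <- ifelse(surv, "selected", "dropped_outlier")
    }
  }

  pts <- points[, c("x", "y", "z", "sensor_id", "t")]
  pts$ref_id <- ref_id
  pts$i_az <- i_az
  pts$i_el <- i_el
  pts$r <- r
  pts$status <- status
  n_sel_stage <- sum(status %in% c("selected", "dropped_outlier"))
  new_validated_cloud(pts, refs, config, n, n_sel_stage, sum(status == "selected"))
}

new_validated_cloud <- function(points, refs, config, n_raw, n_after_selection, n_kept) {
  structure(list(points = points, refs = refs, config = config,
                 n_raw = as.integer(n_raw),
                 n_after_selection = as.integer(n_after_selection),
                 n_kept = as.integer(n_kept)),
            class = "validated_cloud")
}

#' Extract the validated (kept) points of a filtered cloud
#'
#' @param cloud a `validated_cloud` from [filter_cloud()].
#' @return Data frame of the points with status `selected`, with provenance
#'   columns.
#' @export
kept_points <- function(cloud) {
  stopifnot(inherits(cloud, "validated_cloud"))
  cloud$points[cloud$points$status == "selected", , drop = FALSE]
}

#' @export
print.validated_cloud <- function(x, ...) {
  cat("Validated point cloud\n")
  cat(sprintf("  raw points:        %d\n", x$n_raw))
  cat(sprintf("  after selection:   %d\n", x$n_after_selection))
  cat(sprintf("  kept (validated):  %d\n", x$n_kept))
  if (x$n_raw > 0) {
    cat(sprintf("  selectivity:       %.2f%%\n", selectivity(x$n_raw, x$n_kept)))
  }
  cat(sprintf("  reference points:  %d; fine grid %g deg, coarse grid %g deg\n",
              nrow(x$refs), x$config$fine_grid$angular_size,
              x$config$coarse_grid$angular_size))
  invisible(x)
}

#' @export
summary.validated_cloud <- function(object, ...) {
  tab <- table(object$points$status)
  out <- list(counts = tab, n_raw = object$n_raw, n_kept = object$n_kept,
              selectivity = if (object$n_raw > 0) selectivity(object$n_raw, object$n_kept) else NA_real_,
              per_reference = table(object$points$ref_id[object$points$status == "selected"]))
  class(out) <- "summary.validated_cloud"
  out
}

#' @export
print.summary.validated_cloud <- function(x, ...) {
  cat("Validated point cloud summary\n")
  print(x$counts)
  cat(sprintf("selectivity: %.2f%%\n", x$selectivity))
  cat("kept points per reference:\n")
  print(x$per_reference)
  invisible(x)
}

#' Plot a validated cloud as three orthogonal projections
#'
#' @param x a `validated_cloud`.
#' @param which_status statuses to show (default kept points only).
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.validated_cloud <- function(x, which_status = "selected", ...) {
  pts <- x$points[x$points$status %in% which_status, , drop = FALSE]
  if (nrow(pts) == 0) stop("nothing to plot for the requested statuses")
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(pts$x, pts$y, asp = 1, pch = 16, cex = 0.4,
                 xlab = "x [mm]", ylab = "y [mm]", main = "top", ...)
  graphics::plot(pts$x, pts$z, asp = 1, pch = 16, cex = 0.4,
                 xlab = "x [mm]", ylab = "z [mm]", main = "side", ...)
  graphics::plot(pts$y, pts$z, asp = 1, pch = 16, cex = 0.4,
                 xlab = "y [mm]", ylab = "z [mm]", main = "front", ...)
  invisible(x)
}
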