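# Quality metrics for validated clouds: distance to ground truth
# (analytic surface or triangle mesh), selectivity curves, and confusion
# counts against simulator labels.

as_point_matrix <- function(cloud) {
  if (inherits(cloud, "validated_cloud")) {
    p <- kept_points(cloud)
    return(as.matrix(p[, c("x", "y", "z")]))
  }
  if (is.data.frame(cloud)) return(as.matrix(cloud[, c("x", "y", "z")]))
  m <- rbind(cloud)
  stopifnot(ncol(m) == 3)
  m
}

new_distance_report <- function(d) {
  structure(list(distances = d, mean = mean(d), median = stats::median(d),
                 max = max(d), count = length(d)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("Distance report over %d points [mm]: mean %.4g, median %.4g, max %.4g\n",
              x$count, x$mean, x$median, x$max))
  invisible(x)
}

#' Per-point distances from a cloud to an analytic surface model
#'
#' @param cloud a `validated_cloud` (its kept points are used), a data
#'   frame with `x`, `y`, `z`, or a point matrix.
#' @param model a `surface_model`.
#' @return A `distance_report` with per-point distances and summary
#'   statistics (mean, median, max, count), all in mm.
#' @export
cloud_to_model_distances <- function(cloud, model) {
  p <- as_point_matrix(cloud)
  if (nrow(p) == 0) stop("empty cloud: no distances to compute")
  new_distance_report(surface_distance(model, p))
}

#' Per-point distances from a cloud to a triangle mesh
#'
#' Exact point-to-triangle minimum distance (faces, edges and vertices all
#' considered — never a vertex-only shortcut, which would bias means
#' upward), with bounding-sphere pruning per triangle for speed. This is
#' the cloud/mesh comparison used to benchmark scans against a mesh from
#' an optical scanner.
#'
#' @param cloud a `validated_cloud`, data frame or point matrix.
#' @param mesh a `triangle_mesh` from [read_mesh()] or [triangle_mesh()].
#' @return A `distance_report` in mm (mesh units).
#' @export
cloud_to_mesh_distances <- function(cloud, mesh) {
  p <- as_point_matrix(cloud)
  if (nrow(p) == 0) stop("empty cloud: no distances to compute")
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) stop("empty mesh: no triangles")
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(p)
  best <- rep(Inf, n)
  # triangle centroids and circumscribing radii for pruning
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  cent <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - cent)^2), rowSums((B - cent)^2),
                   rowSums((C - cent)^2)))
  # visit triangles nearest-centroid-first from the cloud centroid so the
  # running minimum prunes aggressively
  pc <- colMeans(p)
  ord <- order(rowSums(sweep(cent, 2, pc)^2))
  for (ti in ord) {
    dc <- sqrt((p[, 1] - cent[ti, 1])^2 + (p[, 2] - cent[ti, 2])^2 +
                 (p[, 3] - cent[ti, 3])^2)
    act <- which(dc - rad[ti] < best)
    if (length(act) == 0) next
    d <- point_triangle_distance(p[act, , drop = FALSE],
                                 A[ti, ], B[ti, ], C[ti, ])
    best[act] <- pmin(best[act], d)
  }
  new_distance_report(best)
}

# Exact closest distance from points P (n x 3) to triangle (a, b, c).
# Vectorized port of the standard closest-point-on-triangle region test.
point_triangle_distance <- function(P, a, b, c) {
  P <- rbind(P)
  n <- nrow(P)
  ab <- b - a; ac <- c - a; bc <- c - b
  ap <- sweep(P, 2, a)
  bp <- sweep(P, 2, b)
  cp <- sweep(P, 2, c)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  d3 <- bp %*% ab; d4 <- bp %*% ac
  d5 <- cp %*% ab; d6 <- cp %*% ac
  d1 <- d1[, 1]; d2 <- d2[, 1]; d3 <- d3[, 1]
  d4 <- d4[, 1]; d5 <- d5[, 1]; d6 <- d6[, 1]
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  closest <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set_rows <- function(mask, pts) {
    if (any(mask)) {
      closest[mask, ] <<- pts
      done[mask] <<- TRUE
    }
  }
  m <- !done & d1 <= 0 & d2 <= 0
  set_rows(m, matrix(a, sum(m), 3, byrow = TRUE))
  m <- !done & d3 >= 0 & d4 <= d3
  set_rows(m, matrix(b, sum(m), 3, byrow = TRUE))
  m <- !done & d6 >= 0 & d5 <= d6
  set_rows(m, matrix(c, sum(m), 3, byrow = TRUE))
  m <- !done & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(m)) {
    t_ <- d1[m] / (d1[m] - d3[m])
    set_rows(m, sweep(outer(t_, ab), 2, a, `+`))
  }
  m <- !done & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(m)) {
    t_ <- d2[m] / (d2[m] - d6[m])
    set_rows(m, sweep(outer(t_, ac), 2, a, `+`))
  }
  m <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(m)) {
    t_ <- (d4[m] - d3[m]) / ((d4[m] - d3[m]) + (d5[m] - d6[m]))
    set_rows(m, sweep(outer(t_, bc), 2, b, `+`))
  }
  m <- !done
  if (any(m)) {
    denom <- va[m] + vb[m] + vc[m]
    vv <- vb[m] / denom
    ww <- vc[m] / denom
    set_rows(m, sweep(outer(vv, ab) + outer(ww, ac), 2, a, `+`))
  }
  sqrt(rowSums((P - closest)^2))
}

#' Nearest-neighbour distances between two point sets
#'
#' For each query point, the Euclidean distance to the closest target
#' point, computed in blocks with BLAS matrix products.
#'
#' @param query numeric matrix (n x 3).
#' @param target numeric matrix (m x 3), non-empty.
#' @return Numeric vector of length n.
#' @export
nearest_point_distances <- function(query, target) {
  query <- rbind(query); target <- rbind(target)
  if (nrow(target) == 0) stop("empty target point set")
  t2 <- rowSums(target^2)
  out <- numeric(nrow(query))
  block <- 2048L
  for (start in seq(1, nrow(query), by = block)) {
    idx <- start:min(start + block - 1, nrow(query))
    q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), t2, `+`) - 2 * tcrossprod(q, target)
    best <- max.col(-d2, ties.method = "first")
    out[idx] <- sqrt(pmax(0, d2[cbind(seq_along(idx), best)]))
  }
  out
}

#' Coverage of a surface by a validated cloud
#'
#' Samples probe points on the ground-truth surface and measures each
#' probe's distance to the nearest retained point. Large values expose
#' coverage holes — the resolution loss that appears when the vector from
#' the reference point to the surface becomes highly oblique, which is
#' what motivates using several reference points on elongated objects.
#'
#' @param model a `surface_model`.
#' @param cloud a `validated_cloud`, data frame or point matrix.
#' @param n_probe number of surface probe points.
#' @param seed seed for the probe sampling (default 1).
#' @return A `distance_report` of surface-to-cloud distances in mm.
#' @export
surface_coverage_distances <- function(model, cloud, n_probe = 20000,
                                       seed = 1) {
  p <- as_point_matrix(cloud)
  if (nrow(p) == 0) stop("empty cloud: no coverage to compute")
  probes <- with_seed(seed, surface_sample(model, n_probe)$points)
  new_distance_report(nearest_point_distances(probes, p))
}

#' Selectivity over a ladder of angular resolutions
#'
#' Runs the full filter once per angular size and records the retained
#' percentage, reproducing the resolution/selectivity trade-off curve:
#' the percentage of retained data falls off sharply as the angular
#' resolution coarsens.
#'
#' @param points raw object-frame point data frame.
#' @param refs reference-point data frame.
#' @param angular_sizes positive angular sizes in degrees, ascending.
#' @param config template [filter_config()] supplying the coarse factor,
#'   threshold and occupancy minimum.
#' @return An object of class `selectivity_curve`: data frame with columns
#'   `angular_size` and `retained_pct`.
#' @export
selectivity_sweep <- function(points, refs, angular_sizes,
                              config = filter_config()) {
  stopifnot(length(angular_sizes) >= 1, all(angular_sizes > 0),
            !is.unsorted(angular_sizes))
  pct <- vapply(angular_sizes, function(a) {
    cfg <- filter_config(a, config$coarse_factor, config$outlier_threshold,
                         config$min_sector_count)
    cl <- filter_cloud(points, refs, cfg)
    selectivity(cl$n_raw, cl$n_kept)
  }, numeric(1))
  structure(data.frame(angular_size = angular_sizes, retained_pct = pct),
            class = c("selectivity_curve", "data.frame"))
}

#' @export
plot.selectivity_curve <- function(x, ...) {
  graphics::plot(x$angular_size, x$retained_pct, type = "b", pch = 16,
                 xlab = "sector angular size [deg]",
                 ylab = "retained data [%]", ylim = c(0, 100), ...)
  invisible(x)
}

#' Confusion counts of the filter against simulator truth labels
#'
#' Cross-tabulates kept/dropped filter status against on-surface /
#' off-surface ground truth. Transit points and gross outliers both count
#' as non-surface.
#'
#' @param cloud a `validated_cloud` whose points align one-to-one with
#'   `labels`.
#' @param labels character vector of truth labels (`surface`, `transit`,
#'   `gross_outlier`), one per raw sample in filter input order.
#' @return List of class `label_confusion` with the 2x2 `counts` matrix and
#'   derived rates: `kept_nonsurface_rate` (fraction of kept points that
#'   are off-surface) and `surface_recall` (fraction of surface points
#'   kept).
#' @export
label_confusion <- function(cloud, labels) {
  stopifnot(inherits(cloud, "validated_cloud"))
  if (length(labels) != nrow(cloud$points)) {
    stop("labels (", length(labels), ") do not align with raw samples (",
         nrow(cloud$points), ")")
  }
  kept <- cloud$points$status == "selected"
  surf <- labels == "surface"
  counts <- matrix(c(sum(kept & surf), sum(kept & !surf),
                     sum(!kept & surf), sum(!kept & !surf)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("kept", "dropped"),
                                   c("surface", "nonsurface")))
  structure(list(
    counts = counts,
    kept_nonsurface_rate = if (sum(kept) > 0) sum(kept & !surf) / sum(kept) else NA_real_,
    surface_recall = if (sum(surf) > 0) sum(kept & surf) / sum(surf) else NA_real_
  ), class = "label_confusion")
}

#' @export
print.label_confusion <- function(x, ...) {
  print(x$counts)
  cat(sprintf("kept-nonsurface rate: %.3f%%; surface recall: %.2f%%\n",
              100 * x$kept_nonsurface_rate, 100 * x$surface_recall))
  invisible(x)
}

#' Plot a histogram of cloud-to-surface distances
#'
#' @param x a `distance_report`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.distance_report <- function(x, ...) {
  graphics::hist(x$distances, xlab = "distance to ground truth [mm]",
                 main = "cloud-to-surface distances", ...)
  invisible(x)
}
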