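# Parametric ground-truth surfaces for the scan simulator and evaluation.
#
# Each model is a union of analytic primitives (spheres and capped elliptic
# cylinders); every primitive carries an exact unsigned point-to-surface
# distance, an inside predicate, a surface sampler and an outward normal.
# The union distance is the minimum over primitive distances: exact for
# points outside the solid (the regime the filter cares about), and a
# nearest-component-wall bound for interior points.

# ---- 2D point-to-ellipse distance -------------------------------------

# Unsigned distance from 2D points (u, v) to the ellipse (u/a)^2+(v/b)^2=1.
# Circle shortcut is closed-form; the general case minimizes the squared
# distance over the parameter angle in the first quadrant (unimodal there),
# which is accurate to machine precision in the distance because the error
# is quadratic in the angle.
point_ellipse_distance <- function(u, v, a, b) {
  if (abs(a - b) < 1e-12 * max(a, b)) {
    return(abs(sqrt(u^2 + v^2) - a))
  }
  au <- abs(u); av <- abs(v)
  vapply(seq_along(au), function(i) {
    f <- function(th) {
      du <- a * cos(th) - au[i]
      dv <- b * sin(th) - av[i]
      du * du + dv * dv
    }
    opt <- stats::optimize(f, c(0, pi / 2), tol = 1e-12)
    cand <- sqrt(min(opt$objective, f(0), f(pi / 2)))
    cand
  }, numeric(1))
}

# ---- primitives -------------------------------------------------------

prim_sphere <- function(center, radius) {
  list(kind = "sphere", center = as.numeric(center), radius = radius)
}

# Capped elliptic cylinder with axis along coordinate `axis` (1, 2 or 3),
# axial extent [lo, hi], cross-section semi-axes (a, b) over the two
# remaining coordinates in ascending order, centred on `center2` in the
# cross-section plane.
prim_ecyl <- function(axis, lo, hi, a, b, center2 = c(0, 0)) {
  list(kind = "ecyl", axis = axis, lo = lo, hi = hi, a = a, b = b,
       center2 = as.numeric(center2))
}

ecyl_split <- function(prim, p) {
  tr <- setdiff(1:3, prim$axis)
  list(ax = p[, prim$axis],
       u = p[, tr[1]] - prim$center2[1],
       v = p[, tr[2]] - prim$center2[2],
       tr = tr)
}

prim_distance <- function(prim, p) {
  p <- rbind(p)
  if (prim$kind == "sphere") {
    d <- sweep(p, 2, prim$center)
    return(abs(sqrt(rowSums(d^2)) - prim$radius))
  }
  s <- ecyl_split(prim, p)
  d_ell <- point_ellipse_distance(s$u, s$v, prim$a, prim$b)
  inside_xy <- (s$u / prim$a)^2 + (s$v / prim$b)^2 <= 1
  below <- s$ax < prim$lo
  above <- s$ax > prim$hi
  axdist <- pmax(prim$lo - s$ax, s$ax - prim$hi, 0)
  out <- numeric(nrow(p))
  mid <- !below & !above
  out[mid & !inside_xy] <- d_ell[mid & !inside_xy]
  ii <- mid & inside_xy  # interior: nearest of lateral wall and the two caps
  out[ii] <- pmin(d_ell[ii], s$ax[ii] - prim$lo, prim$hi - s$ax[ii])
  oo <- !mid
  out[oo & inside_xy] <- axdist[oo & inside_xy]
  orim <- oo & !inside_xy
  out[orim] <- sqrt(axdist[orim]^2 + d_ell[orim]^2)
  out
}

prim_inside <- function(prim, p, tol = 1e-9) {
  p <- rbind(p)
  if (prim$kind == "sphere") {
    d <- sweep(p, 2, prim$center)
    return(sqrt(rowSums(d^2)) < prim$radius - tol)
  }
  s <- ecyl_split(prim, p)
  s$ax > prim$lo + tol & s$ax < prim$hi - tol &
    (s$u / prim$a)^2 + (s$v / prim$b)^2 < (1 - tol / max(prim$a, prim$b))^2
}

# Approximate surface area, used only to weight sampling across primitives.
prim_area <- function(prim) {
  if (prim$kind == "sphere") return(4 * pi * prim$radius^2)
  h <- prim$hi - prim$lo
  per <- pi * (3 * (prim$a + prim$b) -
                 sqrt((3 * prim$a + prim$b) * (prim$a + 3 * prim$b)))
  per * h + 2 * pi * prim$a * prim$b
}

# n exact surface points with outward unit normals. Sampling density is
# only approximately uniform (angle-uniform on the ellipse), which is
# irrelevant to correctness: points are exactly on the surface.
prim_sample <- function(prim, n) {
  if (prim$kind == "sphere") {
    g <- matrix(stats::rnorm(3 * n), ncol = 3)
    nr <- sqrt(rowSums(g^2))
    nrm <- g / nr
    pts <- sweep(nrm * prim$radius, 2, prim$center, `+`)
    return(list(points = pts, normals = nrm))
  }
  h <- prim$hi - prim$lo
  per <- pi * (3 * (prim$a + prim$b) -
                 sqrt((3 * prim$a + prim$b) * (prim$a + 3 * prim$b)))
  w <- c(per * h, pi * prim$a * prim$b, pi * prim$a * prim$b)
  part <- sample.int(3, n, replace = TRUE, prob = w)
  pts <- matrix(0, n, 3)
  nrm <- matrix(0, n, 3)
  tr <- setdiff(1:3, prim$axis)
  lat <- part == 1
  nlat <- sum(lat)
  if (nlat > 0) {
    th <- stats::runif(nlat, 0, 2 * pi)
    u <- prim$a * cos(th); v <- prim$b * sin(th)
    pts[lat, prim$axis] <- stats::runif(nlat, prim$lo, prim$hi)
    pts[lat, tr[1]] <- u + prim$center2[1]
    pts[lat, tr[2]] <- v + prim$center2[2]
    nu <- u / prim$a^2; nv <- v / prim$b^2
    nn <- sqrt(nu^2 + nv^2)
    nrm[lat, tr[1]] <- nu / nn
    nrm[lat, tr[2]] <- nv / nn
  }
  for (capi in 2:3) {
    cap <- part == capi
    ncap <- sum(cap)
    if (ncap == 0) next
    th <- stats::runif(ncap, 0, 2 * pi)
    rad <- sqrt(stats::runif(ncap))
    pts[cap, prim$axis] <- if (capi == 2) prim$lo else prim$hi
    pts[cap, tr[1]] <- prim$a * rad * cos(th) + prim$center2[1]
    pts[cap, tr[2]] <- prim$b * rad * sin(th) + prim$center2[2]
    nrm[cap, prim$axis] <- if (capi == 2) -1 else 1
  }
  list(points = pts, normals = nrm)
}

# ---- surface models ---------------------------------------------------

new_surface_model <- function(kind, primitives, params, ref_anchors) {
  structure(list(kind = kind, primitives = primitives, params = params,
                 ref_anchors = ref_anchors),
            class = "surface_model")
}

#' Sphere surface model
#'
#' @param radius sphere radius in mm.
#' @param center centre in mm (object frame).
#' @return A `surface_model`.
#' @export
surface_sphere <- function(radius = 100, center = c(0, 0, 0)) {
  stopifnot(radius > 0)
  new_surface_model("sphere", list(prim_sphere(center, radius)),
                    list(radius = radius, center = center),
                    rbind(center))
}

#' Capped circular cylinder surface model
#'
#' Axis along +z from z = 0 to z = height. The defaults match a test
#' cylinder approximately 7 cm in diameter and 20 cm high.
#'
#' @param radius cylinder radius in mm.
#' @param height cylinder height in mm.
#' @return A `surface_model`.
#' @export
surface_cylinder <- function(radius = 35, height = 200) {
  stopifnot(radius > 0, height > 0)
  new_surface_model("capped_cylinder",
                    list(prim_ecyl(3, 0, height, radius, radius)),
                    list(radius = radius, height = height),
                    NULL)  # axial anchors generated on demand
}

#' Foot-like composite surface model
#'
#' A blobby analogue of a model foot built from analytic primitives: a heel
#' sphere at the origin, an elliptic-cylinder sole running along +x, a toe
#' sphere capping the far end (radius set by `toe_taper`), and an ankle
#' sphere rising above the heel. Exact component distances make it a useful
#' ground truth even though it is not anatomical.
#'
#' @param heel_radius heel sphere radius, mm.
#' @param sole_length distance from heel centre to toe centre, mm.
#' @param sole_width,sole_height elliptic sole cross-section diameters, mm.
#' @param toe_taper toe sphere radius as a fraction of the sole half-height.
#' @return A `surface_model`.
#' @export
surface_foot <- function(heel_radius = 55, sole_length = 180,
                         sole_width = 80, sole_height = 70,
                         toe_taper = 0.8) {
  stopifnot(heel_radius > 0, sole_length > 0, sole_width > 0,
            sole_height > 0, toe_taper > 0, toe_taper <= 1)
  toe_radius <- toe_taper * sole_height / 2
  ankle_radius <- 0.6 * heel_radius
  prims <- list(
    heel = prim_sphere(c(0, 0, 0), heel_radius),
    sole = prim_ecyl(1, 0, sole_length, sole_width / 2, sole_height / 2),
    toe = prim_sphere(c(sole_length, 0, 0), toe_radius),
    ankle = prim_sphere(c(0, 0, heel_radius), ankle_radius)
  )
  # anchors: bridge of the foot, ankle, heel, toe — all strictly interior
  anchors <- rbind(
    bridge = c(0.55 * sole_length, 0, 0),
    ankle = c(0, 0, 0.9 * heel_radius),
    heel = c(-0.3 * heel_radius, 0, 0),
    toe = c(sole_length, 0, 0)
  )
  new_surface_model("foot_like", prims,
                    list(heel_radius = heel_radius, sole_length = sole_length,
                         sole_width = sole_width, sole_height = sole_height,
                         toe_taper = toe_taper, toe_radius = toe_radius,
                         ankle_radius = ankle_radius),
                    anchors)
}

#' @export
print.surface_model <- function(x, ...) {
  cat("Surface model:", x$kind, "\n")
  cat("  parameters:", paste(names(x$params),
                             vapply(x$params, function(p) paste(format(p), collapse = ","),
                                    character(1)),
                             sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Unsigned distance from points to a surface model
#'
#' Minimum over the model's analytic primitives. Exact for points outside
#' the solid; for interior points it returns the distance to the nearest
#' component wall, which can undercut the distance to the union boundary
#' near internal seams.
#'
#' @param model a `surface_model`.
#' @param p numeric matrix of points (one per row, mm) or a 3-vector.
#' @return Numeric vector of distances in mm.
#' @export
surface_distance <- function(model, p) {
  stopifnot(inherits(model, "surface_model"))
  p <- rbind(p)
  d <- vapply(model$primitives, function(pr) prim_distance(pr, p),
              numeric(nrow(p)))
  d <- matrix(d, nrow = nrow(p))
  apply(d, 1, min)
}

# TRUE for points strictly inside the union solid.
surface_inside <- function(model, p, tol = 1e-9) {
  p <- rbind(p)
  ins <- rep(FALSE, nrow(p))
  for (pr in model$primitives) ins <- ins | prim_inside(pr, p, tol)
  ins
}

#' Sample exact surface points with outward normals
#'
#' Draws points on the union surface: primitive surfaces are sampled
#' proportionally to area and points falling strictly inside another
#' primitive are rejected. Uses the current RNG state.
#'
#' @param model a `surface_model`.
#' @param n number of points.
#' @return List with `points` (n x 3) and `normals` (n x 3, unit outward).
#' @export
surface_sample <- function(model, n) {
  areas <- vapply(model$primitives, prim_area, numeric(1))
  pts <- matrix(numeric(0), 0, 3)
  nrm <- matrix(numeric(0), 0, 3)
  guard <- 0
  while (nrow(pts) < n) {
    need <- n - nrow(pts)
    draw <- ceiling(need * 1.5) + 8
    which_prim <- sample.int(length(model$primitives), draw,
                             replace = TRUE, prob = areas)
    for (k in seq_along(model$primitives)) {
      nk <- sum(which_prim == k)
      if (nk == 0) next
      smp <- prim_sample(model$primitives[[k]], nk)
      others <- model$primitives[-k]
      bad <- rep(FALSE, nk)
      for (pr in others) bad <- bad | prim_inside(pr, smp$points, tol = 1e-9)
      pts <- rbind(pts, smp$points[!bad, , drop = FALSE])
      nrm <- rbind(nrm, smp$normals[!bad, , drop = FALSE])
    }
    guard <- guard + 1
    if (guard > 100) stop("surface sampling failed to converge")
  }
  sel <- seq_len(n)
  list(points = pts[sel, , drop = FALSE], normals = nrm[sel, , drop = FALSE])
}

#' Place reference points inside a surface model
#'
#' Returns k origins strictly interior to the model: the centre for a
#' sphere; evenly spaced axial points for a cylinder (for k = 2, at one
#' quarter and three quarters of the height); and for the foot-like model
#' the anchor sequence bridge, ankle, heel, toe (for k = 2: one near the
#' bridge of the foot and one near the ankle).
#'
#' @param model a `surface_model`.
#' @param k number of reference points (>= 1).
#' @return A [reference_points()] data frame.
#' @export
plant_reference_points <- function(model, k = 1) {
  stopifnot(inherits(model, "surface_model"), k >= 1)
  if (model$kind == "sphere") {
    if (k > 1) stop("a sphere has a single interior anchor (its centre)")
    return(reference_points(rbind(model$params$center)))
  }
  if (model$kind == "capped_cylinder") {
    h <- model$params$height
    heights <- h * (2 * seq_len(k) - 1) / (2 * k)
    return(reference_points(cbind(0, 0, heights)))
  }
  if (k > nrow(model$ref_anchors)) {
    stop("only ", nrow(model$ref_anchors), " interior anchors are available")
  }
  reference_points(model$ref_anchors[seq_len(k), , drop = FALSE])
}
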