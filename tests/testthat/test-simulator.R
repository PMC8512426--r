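test_that("analytic surface distances match elementary geometry", {
  sph <- surface_sphere(1)
  expect_equal(surface_distance(sph, c(1, 0, 0)), 0)
  expect_equal(surface_distance(sph, c(0, 0, 2)), 1)
  cyl <- surface_cylinder(35, 200)  # the 7 cm x 20 cm test cylinder
  expect_equal(surface_distance(cyl, c(0, 0, 100)), 35)        # axis, mid-height
  expect_equal(surface_distance(cyl, c(0, 0, 250)), 50)        # above the cap
  expect_equal(surface_distance(cyl, c(50, 0, 100)), 15)       # outside lateral
  expect_equal(surface_distance(cyl, c(60, 0, 220)),
               sqrt(25^2 + 20^2))                              # rim corner
})

test_that("elliptic-cylinder distance agrees with a dense boundary oracle", {
  prim <- sectorscan:::prim_ecyl(3, 0, 50, a = 40, b = 25)
  # oracle boundary sampling: lateral surface grid plus both cap discs
  th <- seq(0, 2 * pi, length.out = 4001)[-1]
  zs <- seq(0, 50, length.out = 101)
  g <- expand.grid(th = th, z = zs)
  lat <- cbind(40 * cos(g$th), 25 * sin(g$th), g$z)
  cg <- expand.grid(s = sqrt(seq(0, 1, length.out = 80)),
                    th = th[seq(1, 4000, by = 5)], z = c(0, 50))
  caps <- cbind(40 * cg$s * cos(cg$th), 25 * cg$s * sin(cg$th), cg$z)
  boundary <- rbind(lat, caps)

  set.seed(6)
  pts <- cbind(stats::runif(40, -60, 60), stats::runif(40, -60, 60),
               stats::runif(40, -20, 70))
  d_pkg <- sectorscan:::prim_distance(prim, pts)
  d_oracle <- nearest_point_distances(pts, boundary)
  expect_true(all(d_pkg <= d_oracle + 1e-9))  # exact never exceeds sampled
  expect_lt(max(d_oracle - d_pkg), 0.2)       # and is close at this density
})

test_that("sampled surface points lie on the surface with outward normals", {
  set.seed(12)
  for (model in list(surface_sphere(100), surface_cylinder(35, 200),
                     surface_foot())) {
    smp <- surface_sample(model, 500)
    # distance is measured back through a 1-D optimizer for elliptic
    # primitives, so the verification floor is its tolerance, not 1e-12
    expect_lt(max(surface_distance(model, smp$points)), 1e-5)
    expect_equal(rowSums(smp$normals^2), rep(1, 500), tolerance = 1e-9)
    # stepping outward along the normal leaves the solid and raises distance
    out <- smp$points + 5 * smp$normals
    expect_true(all(!sectorscan:::surface_inside(model, out)))
  }
})

test_that("reference points are planted strictly inside at the stated anchors", {
  expect_equal(unlist(plant_reference_points(surface_sphere(50, c(1, 2, 3)))[, c("x", "y", "z")]),
               c(x = 1, y = 2, z = 3))
  expect_error(plant_reference_points(surface_sphere(50), 2), "anchor")
  cyl2 <- plant_reference_points(surface_cylinder(35, 200), 2)
  expect_equal(cyl2$z, c(50, 150))  # h/4 and 3h/4
  expect_equal(plant_reference_points(surface_cylinder(35, 200), 1)$z, 100)
  foot <- surface_foot()
  refs <- plant_reference_points(foot, 2)
  expect_true(all(sectorscan:::surface_inside(foot, as.matrix(refs[, c("x", "y", "z")]))))
  expect_true(all(surface_distance(foot, as.matrix(refs[, c("x", "y", "z")])) > 0))
  expect_error(plant_reference_points(foot, 10), "anchors")
})

test_that("traces are deterministic given the seed and respect label fractions", {
  model <- surface_sphere(100)
  cfg <- trace_config(n_samples = 2000, fraction_transit = 0.5, seed = 5)
  t1 <- generate_trace(model, cfg)
  t2 <- generate_trace(model, cfg)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$labels, t2$labels)

  cfg2 <- trace_config(n_samples = 10000, fraction_transit = 0.5,
                       gross_outlier_rate = 0, seed = 9)
  tr <- generate_trace(model, cfg2)
  frac <- mean(tr$labels == "transit")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(trace_config(n_samples = 10), "seed")
})

test_that("emitted labels are consistent with geometry", {
  model <- surface_cylinder(35, 200)
  cfg <- trace_config(n_samples = 4000, fraction_transit = 0.4,
                      lift_range = c(10, 60), noise_sigma = 0.8,
                      gross_outlier_rate = 0.02,
                      gross_outlier_magnitude = 300, seed = 17)
  tr <- generate_trace(model, cfg)
  d <- surface_distance(model, tr$static_points)
  expect_lt(max(d[tr$labels == "surface"]), 0.8 * 6)  # noise-level distances
  expect_gt(min(d[tr$labels == "transit"]), 10 - 3 * 0.8 * sqrt(3))
  expect_gt(mean(d[tr$labels == "gross_outlier"] > 20), 0.95)

  noise_free <- generate_trace(model,
    trace_config(n_samples = 3000, fraction_transit = 0, noise_sigma = 0,
                 gross_outlier_rate = 0, seed = 3))
  expect_lt(max(surface_distance(model, noise_free$static_points)), 1e-9)
})

test_that("per-axis sigma reproduces the specified 3-D RMS error", {
  model <- surface_sphere(100)
  n <- 20000
  noisy <- generate_trace(model, trace_config(n_samples = n, fraction_transit = 0,
                                              gross_outlier_rate = 0, seed = 13))
  clean <- generate_trace(model, trace_config(n_samples = n, fraction_transit = 0,
                                              gross_outlier_rate = 0,
                                              noise_sigma = 0, seed = 13))
  rms <- sqrt(mean(rowSums((noisy$static_points - clean$static_points)^2)))
  expect_equal(rms, 1.4, tolerance = 0.05)
})

test_that("rigid motion is identity at t = 0 and compensates exactly", {
  mot <- rigid_motion(axis = c(0, 1, 1), rate_deg_s = 30,
                      velocity = c(20, 0, 0), pivot = c(5, 5, 5))
  p <- rbind(c(10, 20, 30))
  expect_equal(apply_motion(mot, p, 0), p)

  model <- surface_cylinder(35, 200)
  cfg <- trace_config(n_samples = 2000, fraction_transit = 0.3, seed = 9)
  st <- generate_trace(model, cfg)
  mv <- generate_trace(model, cfg, motion = mot)
  ps <- to_object_frame(st$samples, st$ref_stream)
  pm <- to_object_frame(mv$samples, mv$ref_stream)
  expect_lt(max(abs(as.matrix(ps[, 1:3]) - as.matrix(pm[, 1:3]))), 1e-6)
  expect_error(rigid_motion(axis = c(0, 0, 0)), "axis")
})

test_that("trace generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generate_trace(surface_sphere(10),
                           trace_config(n_samples = 50, seed = 1)))
  expect_identical(stats::runif(1), before)
})
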