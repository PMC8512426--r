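test_that("sector indexing floors, wraps azimuth and clamps the pole", {
  g5 <- sector_grid(5)
  expect_equal(g5$n_az, 72)
  expect_equal(g5$n_el, 36)
  expect_equal(unlist(sector_index(0, -90, g5)), c(i_az = 0L, i_el = 0L))
  expect_equal(unlist(sector_index(359.9, 89.9, g5)), c(i_az = 71L, i_el = 35L))
  expect_equal(sector_index(0, 90, g5)$i_el, 35L)   # pole clamps into top row
  expect_equal(sector_index(360, 0, g5)$i_az, 0L)   # azimuth wraps
  g7 <- sector_grid(7)  # non-divisor size still covers every direction
  idx <- sector_index(c(0, 359.99), c(-90, 90), g7)
  expect_true(all(idx$i_az >= 0 & idx$i_az < g7$n_az))
  expect_true(all(idx$i_el >= 0 & idx$i_el < g7$n_el))
  expect_error(sector_grid(0), "angular_size")
  expect_error(sector_grid(95), "angular_size")
})

test_that("points go to the nearest reference, ties to the lowest id", {
  refs <- reference_points(rbind(c(0, 0, 0), c(100, 0, 0)))
  pts <- data.frame(x = c(10, 90, 50), y = 0, z = 0)
  expect_equal(assign_to_nearest_reference(pts, refs), c(1L, 2L, 1L))
  one <- reference_points(c(5, 5, 5))
  expect_equal(assign_to_nearest_reference(pts, one), rep(1L, 3))
  expect_error(assign_to_nearest_reference(pts, one[0, ]), "reference")
})

test_that("per-sector selection matches the brute-force oracle exactly", {
  set.seed(101)
  for (rep_i in 1:5) {
    pts <- random_cloud(200)
    origin <- c(0, 0, 0)
    for (delta in c(1, 5, 10, 30)) {
      keep <- select_closest_per_sector(pts, origin, sector_grid(delta))
      expect_identical(which(keep), brute_select_ids(pts, origin, delta))
    }
  }
})

test_that("selection keeps the closer of collinear points and is idempotent", {
  pts <- data.frame(x = c(10, 20), y = 0, z = 0, sensor_id = 1:2, t = c(1, 2))
  keep <- select_closest_per_sector(pts, c(0, 0, 0), sector_grid(10))
  expect_identical(keep, c(TRUE, FALSE))

  set.seed(33)
  pts <- random_cloud(300)
  g <- sector_grid(10)
  k1 <- select_closest_per_sector(pts, c(0, 0, 0), g)
  once <- pts[k1, ]
  k2 <- select_closest_per_sector(once, c(0, 0, 0), g)
  expect_true(all(k2))  # selecting the already-selected changes nothing

  # points pre-placed one per sector all survive
  sph <- data.frame(az = seq(5, 355, by = 20), el = rep(c(-45, 45), 9))
  p <- spherical_to_cart(50, sph$az, sph$el)
  pre <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                    sensor_id = 1L, t = seq_len(nrow(p)))
  expect_true(all(select_closest_per_sector(pre, c(0, 0, 0), sector_grid(20))))
})

test_that("radius ties break by earliest time then lowest sensor id", {
  pts <- data.frame(x = c(10, 10, 10), y = 0, z = 0,
                    sensor_id = c(3L, 1L, 2L), t = c(2, 1, 1))
  keep <- select_closest_per_sector(pts, c(0, 0, 0), sector_grid(10))
  expect_identical(which(keep), 2L)  # t = 1 and sensor 1 beats sensor 2
})

test_that("the 20% outlier rule matches direct arithmetic", {
  mk <- function(radii) data.frame(x = radii, y = 0.1 * seq_along(radii), z = 0,
                                   sensor_id = 1L, t = seq_along(radii))
  g <- sector_grid(30)
  # mean 107.5, cutoff 129: the 130 point is eliminated
  keep <- reject_outliers(mk(c(100, 100, 100, 130)), c(0, 0, 0), g, 0.20, 3)
  expect_identical(keep, c(TRUE, TRUE, TRUE, FALSE))
  # mean 106.25, cutoff 127.5: all survive
  keep <- reject_outliers(mk(c(100, 100, 100, 125)), c(0, 0, 0), g, 0.20, 3)
  expect_true(all(keep))
  # a lone point in its sector passes through regardless of radius
  lone <- data.frame(x = 0, y = 0, z = 500, sensor_id = 1L, t = 1)
  expect_true(reject_outliers(lone, c(0, 0, 0), g, 0.20, 3))
  expect_error(reject_outliers(mk(c(1, 2)), c(0, 0, 0), g, -0.1, 3), "threshold")
})

test_that("a point at 1.5 times the sector mean is always eliminated", {
  g <- sector_grid(30)
  for (seed in 1:10) {
    set.seed(seed)
    n_good <- sample(3:12, 1)
    r_good <- stats::runif(n_good, 95, 105)
    # same direction cluster: planted radius 1.5 x mean of the well-behaved
    az <- stats::runif(1, 40, 50); el <- stats::runif(1, 10, 20)
    p <- spherical_to_cart(c(r_good, 1.5 * mean(r_good)), az, el)
    pts <- data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
                      sensor_id = 1L, t = seq_len(n_good + 1))
    keep <- reject_outliers(pts, c(0, 0, 0), g, 0.20, 3)
    expect_false(keep[n_good + 1])
    expect_true(all(keep[seq_len(n_good)]))
  }
})

test_that("the full pipeline carries provenance and respects the sector minimum", {
  refs <- reference_points(rbind(c(0, 0, 0), c(200, 0, 0)))
  set.seed(55)
  pts <- random_cloud(400)
  pts$x <- pts$x + sample(c(0, 200), 400, replace = TRUE)
  cl <- filter_cloud(pts, refs, filter_config(10))
  expect_s3_class(cl, "validated_cloud")
  expect_true(all(cl$points$status %in%
                    c("selected", "dropped_not_closest", "dropped_outlier")))
  expect_equal(nrow(cl$points), 400)
  expect_equal(cl$n_kept, sum(cl$points$status == "selected"))
  # every selected point has minimal radius within its (reference, sector) cell
  P <- cl$points
  key <- paste(P$ref_id, P$i_az, P$i_el)
  for (k in unique(key[P$status == "selected"])) {
    cell <- P[key == k, ]
    expect_equal(min(cell$r), cell$r[cell$status == "selected"][1])
  }
  # volume minimization: kept radius <= every not-closest radius in the cell
  agg <- tapply(P$r[P$status == "dropped_not_closest"],
                key[P$status == "dropped_not_closest"], min)
  sel_r <- tapply(P$r[P$status == "selected"], key[P$status == "selected"], min)
  shared <- intersect(names(agg), names(sel_r))
  expect_true(all(sel_r[shared] <= agg[shared]))
})

test_that("an empty input yields an empty validated cloud", {
  refs <- reference_points(c(0, 0, 0))
  cl <- filter_cloud(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)),
                     refs, filter_config(5))
  expect_equal(cl$n_raw, 0L)
  expect_equal(cl$n_kept, 0L)
  expect_equal(nrow(kept_points(cl)), 0L)
})

test_that("points coincident with a reference are skipped with a warning", {
  refs <- reference_points(c(0, 0, 0))
  pts <- data.frame(x = c(0, 10), y = 0, z = 0, sensor_id = 1L, t = 1:2)
  expect_warning(cl <- filter_cloud(pts, refs, filter_config(10)), "coincide")
  expect_equal(cl$points$status, c("dropped_degenerate", "selected"))
})

test_that("selectivity is plain percentage arithmetic with guarded domain", {
  expect_equal(selectivity(1000, 1000), 100)
  expect_equal(selectivity(1000, 0), 0)
  expect_equal(selectivity(2000, 500), 25)
  expect_error(selectivity(0, 0), "undefined")
  expect_error(selectivity(10, 20), "kept_count")
})

test_that("reference points average the in-window glove sensors only", {
  s <- data.frame(x = c(1, 0, 2, 100, 5), y = c(2, 0, 2, 0, 5),
                  z = c(3, 0, 2, 0, 5),
                  sensor_id = c(1L, 1L, 2L, 0L, 1L),
                  t = c(0.5, 1, 1.5, 1.2, 9))
  expect_equal(unlist(compute_reference_point(s[1, ], c(0, 1))[, c("x", "y", "z")]),
               c(x = 1, y = 2, z = 3))
  rp <- compute_reference_point(s, c(1, 2))  # excludes reference sensor at (100,0,0)
  expect_equal(unlist(rp[, c("x", "y", "z")]), c(x = 1, y = 1, z = 1))
  expect_error(compute_reference_point(s, c(20, 30)), "window")
})
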