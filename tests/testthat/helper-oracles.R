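# Independent oracles and small fixture builders used across the suite.

# Brute-force per-sector minimum selection, written independently of the
# package internals: explicit per-point trigonometry (acos-based elevation)
# and a split/lapply grouping with an O(n^2)-style scan per sector.
brute_select_ids <- function(points, origin, angular_size) {
  n_az <- ceiling(360 / angular_size)
  n_el <- ceiling(180 / angular_size)
  keep <- integer(0)
  keys <- character(nrow(points))
  r <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d <- c(points$x[i], points$y[i], points$z[i]) - origin
    r[i] <- sqrt(sum(d^2))
    if (r[i] == 0) { keys[i] <- NA_character_; next }
    az <- atan2(d[2], d[1]) * 180 / pi
    if (az < 0) az <- az + 360
    el <- 90 - acos(max(-1, min(1, d[3] / r[i]))) * 180 / pi
    ia <- min(floor(az / angular_size), n_az - 1)
    ie <- min(max(floor((el + 90) / angular_size), 0), n_el - 1)
    keys[i] <- paste(ia, ie)
  }
  for (grp in split(seq_len(nrow(points)), keys)) {
    best <- grp[1]
    for (j in grp[-1]) {
      if (r[j] < r[best] ||
          (r[j] == r[best] && points$t[j] < points$t[best]) ||
          (r[j] == r[best] && points$t[j] == points$t[best] &&
             points$sensor_id[j] < points$sensor_id[best])) {
        best <- j
      }
    }
    keep <- c(keep, best)
  }
  sort(keep)
}

# Random object-frame point cloud.
random_cloud <- function(n, scale = 100) {
  data.frame(x = stats::runif(n, -scale, scale),
             y = stats::runif(n, -scale, scale),
             z = stats::runif(n, -scale, scale),
             sensor_id = sample(1:3, n, replace = TRUE),
             t = seq_len(n) / 100)
}

# Rotation matrix from axis-angle via the Rodrigues formula — an
# independent route to the same rotation as a unit quaternion.
rodrigues_matrix <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

axis_angle_quat <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c(cos(angle_rad / 2), sin(angle_rad / 2) * a)
}

# Unit-cube triangle mesh [0,1]^3 built face by face.
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # vertex order: (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1)
  f <- rbind(
    c(1, 2, 4), c(1, 4, 3),  # bottom z=0
    c(5, 8, 6), c(5, 7, 8),  # top z=1
    c(1, 6, 2), c(1, 5, 6),  # y=0
    c(3, 4, 8), c(3, 8, 7),  # y=1
    c(1, 3, 7), c(1, 7, 5),  # x=0
    c(2, 6, 8), c(2, 8, 4)   # x=1
  )
  triangle_mesh(v, f)
}

# Standard noisy foot scan fixture shared by several tests: 30k samples
# over the foot-like model with tracker-level noise.
foot_fixture <- function(n = 30000, seed = 7) {
  model <- surface_foot()
  cfg <- trace_config(n_samples = n, fraction_transit = 0.5, seed = seed)
  trace <- generate_trace(model, cfg)
  list(model = model, trace = trace,
       points = to_object_frame(trace$samples, trace$ref_stream),
       refs = plant_reference_points(model, 2))
}
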