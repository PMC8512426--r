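# File formats and the streaming-session contract.

#' Write pose samples to CSV
#'
#' Fixed dialect: comma separator, dot decimal, UTF-8, mandatory header,
#' columns `t, sensor_id, x, y, z, qw, qx, qy, qz`. Values are written
#' with enough digits to round-trip losslessly at 6 significant digits.
#'
#' @param samples pose-sample data frame.
#' @param path output file path.
#' @export
write_samples_csv <- function(samples, path) {
  samples <- validate_samples(samples)
  out <- samples[, SAMPLE_COLUMNS]
  for (col in setdiff(SAMPLE_COLUMNS, "sensor_id")) {
    out[[col]] <- sprintf("%.10g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read pose samples from CSV
#'
#' Columns are matched by header name, so column order is free. A missing
#' column raises a schema error naming it; a non-numeric cell raises a
#' parse error naming the file line.
#'
#' @param path CSV file path.
#' @return A validated pose-sample data frame (possibly empty).
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    out <- data.frame(t = numeric(0), sensor_id = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      qw = numeric(0), qx = numeric(0), qy = numeric(0),
                      qz = numeric(0))
    return(out)
  }
  out <- df[, SAMPLE_COLUMNS]
  for (col in SAMPLE_COLUMNS) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      stop("parse error in ", path, " line ", bad[1] + 1,
           ": non-numeric value in column ", col)
    }
    out[[col]] <- vals
  }
  out$sensor_id <- as.integer(out$sensor_id)
  validate_samples(out)
}

status_codes <- c(selected = 0L, dropped_not_closest = 1L,
                  dropped_outlier = 2L, dropped_degenerate = 3L)

#' Write a point cloud to disk
#'
#' `xyz` writes whitespace-separated coordinate triples of the kept points;
#' `ply` writes an ascii PLY with a per-vertex integer `status` property
#' encoding the filter provenance (0 selected, 1 dropped in selection,
#' 2 dropped as outlier, 3 degenerate).
#'
#' @param cloud a `validated_cloud`, or a data frame / matrix of points.
#' @param path output path.
#' @param format `"xyz"` or `"ply"`.
#' @param what which statuses to write for a `validated_cloud` (default
#'   kept points only; use `"all"` for every raw point).
#' @export
write_cloud <- function(cloud, path, format = c("xyz", "ply"),
                        what = "selected") {
  format <- match.arg(format)
  if (inherits(cloud, "validated_cloud")) {
    pts <- cloud$points
    if (!identical(what, "all")) pts <- pts[pts$status %in% what, , drop = FALSE]
    status <- status_codes[pts$status]
  } else {
    pts <- as.data.frame(as_point_matrix(cloud))
    names(pts) <- c("x", "y", "z")
    status <- rep(0L, nrow(pts))
  }
  if (format == "xyz") {
    writeLines(sprintf("%.10g %.10g %.10g", pts$x, pts$y, pts$z), path)
    return(invisible(path))
  }
  if (nrow(pts) == 0) stop("refusing to write an empty PLY cloud")
  hdr <- c("ply", "format ascii 1.0",
           "comment sectorscan validated cloud",
           sprintf("element vertex %d", nrow(pts)),
           "property float x", "property float y", "property float z",
           "property int status", "end_header")
  body <- sprintf("%.10g %.10g %.10g %d", pts$x, pts$y, pts$z, status)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a point cloud written by [write_cloud()]
#'
#' @param path `.xyz` or `.ply` file.
#' @return Data frame with columns `x`, `y`, `z` and, for PLY files with a
#'   status property, `status` (decoded to the provenance labels).
#' @export
read_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
    m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
    return(data.frame(x = m[, 1], y = m[, 2], z = m[, 3]))
  }
  if (ext == "ply") {
    mesh <- read_mesh_ply(path)
    out <- data.frame(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                      z = mesh$vertices[, 3])
    if (!is.null(mesh$vertex_properties) && "status" %in% names(mesh$vertex_properties)) {
      out$status <- names(status_codes)[match(mesh$vertex_properties$status, status_codes)]
    }
    return(out)
  }
  stop("unsupported cloud format: .", ext)
}

#' Write a distance report to CSV or JSON
#'
#' @param report a `distance_report`.
#' @param path output path ending in `.csv` (per-point distances plus a
#'   summary attribute block) or `.json`.
#' @export
write_distance_report <- function(report, path) {
  stopifnot(inherits(report, "distance_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(data.frame(distance_mm = report$distances), path,
                     row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(mean_mm = report$mean, median_mm = report$median,
                              max_mm = report$max, count = report$count,
                              distances_mm = report$distances),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported report format: .", ext)
  }
  invisible(path)
}

# ---- streaming session -------------------------------------------------

#' Start a scanning session
#'
#' The session emulates the acquisition/filtering pipeline as a sequential
#' contract: an append-only raw buffer plus on-demand full re-filtering.
#' Appended samples are never lost, each filter pass sees a consistent
#' snapshot of the buffer, and every snapshot is reproducible by
#' re-running the filter on the buffer prefix that produced it. With
#' `refilter_every` set, a re-filter triggers automatically once that many
#' samples have arrived since the last pass, emulating the two-thread
#' acquire/filter pipeline without concurrency.
#'
#' @param refs reference-point data frame.
#' @param config a [filter_config()].
#' @param ref_stream optional reference-sensor stream; when given, appended
#'   samples are interpreted as base-frame poses and are re-expressed in
#'   the object frame before filtering.
#' @param refilter_every optional integer cadence for automatic
#'   re-filtering.
#' @return An object of class `scan_session` (functional: session
#'   modifiers return an updated copy).
#' @export
scan_session <- function(refs, config = filter_config(), ref_stream = NULL,
                         refilter_every = NULL) {
  structure(list(refs = refs, config = config, ref_stream = ref_stream,
                 buffer = NULL, since_filter = 0L,
                 refilter_every = refilter_every, snapshots = list()),
            class = "scan_session")
}

#' Append raw samples to a session
#'
#' @param session a `scan_session`.
#' @param samples pose-sample data frame (base frame when the session has
#'   a reference stream, otherwise already object-frame points).
#' @return The updated session; may contain a new snapshot if the
#'   re-filter cadence elapsed.
#' @export
session_append <- function(session, samples) {
  stopifnot(inherits(session, "scan_session"))
  pts <- if (!is.null(session$ref_stream)) {
    to_object_frame(samples, session$ref_stream)
  } else {
    as.data.frame(samples)[, c("x", "y", "z", "sensor_id", "t")]
  }
  session$buffer <- rbind(session$buffer, pts)
  session$since_filter <- session$since_filter + nrow(pts)
  if (!is.null(session$refilter_every) &&
      session$since_filter >= session$refilter_every) {
    session <- session_refilter(session)
  }
  session
}

#' Re-filter the whole accumulated buffer and record a snapshot
#'
#' @param session a `scan_session`.
#' @return The updated session with a new entry in `snapshots`, each
#'   holding the `validated_cloud`, the buffer length it was computed
#'   from (`n_raw`), and a timestamp.
#' @export
session_refilter <- function(session) {
  stopifnot(inherits(session, "scan_session"))
  if (is.null(session$buffer) || nrow(session$buffer) == 0) {
    stop("session buffer is empty: nothing to filter")
  }
  cloud <- filter_cloud(session$buffer, session$refs, session$config)
  session$snapshots[[length(session$snapshots) + 1]] <-
    list(cloud = cloud, n_raw = nrow(session$buffer), time = Sys.time())
  session$since_filter <- 0L
  session
}

#' @export
print.scan_session <- function(x, ...) {
  cat(sprintf("Scan session: %d buffered samples, %d snapshot(s), %d reference point(s)\n",
              if (is.null(x$buffer)) 0L else nrow(x$buffer),
              length(x$snapshots), nrow(x$refs)))
  invisible(x)
}
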