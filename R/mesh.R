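# Triangle-mesh container and ascii readers (PLY / OBJ / STL).

#' Triangle mesh container
#'
#' @param vertices numeric matrix, one vertex per row (x, y, z).
#' @param faces integer matrix, one triangle per row, 1-based vertex
#'   indices. Polygons with more than three vertices are fan-triangulated.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, all(is.finite(vertices)))
  if (is.list(faces)) faces <- do.call(rbind, lapply(faces, fan_triangulate))
  faces <- as.matrix(faces)
  if (ncol(faces) > 3) faces <- do.call(rbind, apply(faces, 1, fan_triangulate, simplify = FALSE))
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

fan_triangulate <- function(idx) {
  idx <- as.integer(idx)
  if (length(idx) < 3) stop("faces need at least 3 vertices")
  if (length(idx) == 3) return(matrix(idx, 1, 3))
  cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangle mesh from an ascii PLY, OBJ or STL file
#'
#' The format is inferred from the file extension. Only ascii variants are
#' supported; polygonal faces are fan-triangulated. The mesh need not be
#' watertight — it is used purely as a triangle soup for distance
#' evaluation.
#'
#' @param path file path ending in `.ply`, `.obj` or `.stl`.
#' @return A `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_mesh_ply(path),
         obj = read_mesh_obj(path),
         stl = read_mesh_stl(path),
         stop("unsupported mesh format: .", ext, " (use ply, obj or stl)"))
}

read_mesh_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY header missing end_header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (any(grepl("^format\\s+binary", hdr))) stop("binary PLY is not supported")
  elem_lines <- grep("^element\\s", hdr)
  elems <- do.call(rbind, lapply(strsplit(hdr[elem_lines], "\\s+"), function(tok) {
    data.frame(name = tok[2], count = as.integer(tok[3]))
  }))
  # properties of the vertex element, in declaration order
  vert_i <- which(elems$name == "vertex")
  if (length(vert_i) == 0) stop("PLY file has no vertex element")
  vstart <- elem_lines[vert_i]
  vend <- if (vert_i < nrow(elems)) elem_lines[vert_i + 1] - 1 else hdr_end - 1
  vprops <- hdr[(vstart + 1):vend]
  vprops <- vprops[grepl("^property\\s", vprops)]
  vnames <- vapply(strsplit(vprops, "\\s+"), function(x) x[length(x)], character(1))

  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  offset <- 0
  vertices <- NULL; faces <- NULL; vextra <- NULL
  for (i in seq_len(nrow(elems))) {
    cnt <- elems$count[i]
    chunk <- body[offset + seq_len(cnt)]
    offset <- offset + cnt
    tok <- strsplit(trimws(chunk), "\\s+")
    if (elems$name[i] == "vertex") {
      m <- matrix(as.numeric(unlist(tok)), nrow = cnt, byrow = TRUE)
      colnames(m) <- vnames[seq_len(ncol(m))]
      vertices <- m[, c("x", "y", "z"), drop = FALSE]
      vextra <- m[, setdiff(colnames(m), c("x", "y", "z")), drop = FALSE]
    } else if (elems$name[i] == "face") {
      faces <- do.call(rbind, lapply(tok, function(x) {
        k <- as.integer(x[1])
        fan_triangulate(as.integer(x[2:(1 + k)]) + 1L)  # PLY is 0-based
      }))
    }
  }
  if (is.null(vertices)) stop("PLY file contains no vertices")
  mesh <- triangle_mesh(vertices, if (is.null(faces)) matrix(integer(0), 0, 3) else faces)
  if (!is.null(vextra) && ncol(vextra) > 0) mesh$vertex_properties <- as.data.frame(vextra)
  mesh
}

read_mesh_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0) stop("OBJ file contains no vertices")
  vertices <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x) {
    idx <- vapply(x[-1], function(tokn) as.integer(strsplit(tokn, "/")[[1]][1]), integer(1))
    fan_triangulate(idx)
  }))
  triangle_mesh(vertices, if (is.null(faces)) matrix(integer(0), 0, 3) else faces)
}

read_mesh_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (length(lines) == 0 || !startsWith(tolower(lines[1]), "solid")) {
    stop("only ascii STL is supported")
  }
  vlines <- lines[startsWith(tolower(lines), "vertex")]
  if (length(vlines) %% 3 != 0) stop("malformed STL: vertex count not a multiple of 3")
  verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x) as.numeric(x[2:4])))
  nf <- nrow(verts) / 3
  # merge duplicate vertices so the soup has shared topology
  key <- apply(round(verts, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  vertices <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  triangle_mesh(vertices, faces)
}

#' Generate a UV-sphere triangle mesh
#'
#' Latitude/longitude triangulation of a sphere, used as a programmatic
#' mesh fixture and to cross-check mesh distances against the analytic
#' sphere distance (agreement is bounded by the mesh chord error).
#'
#' @param radius sphere radius.
#' @param center sphere centre.
#' @param n_lat number of latitude bands.
#' @param n_lon number of longitude segments.
#' @return A `triangle_mesh`.
#' @export
mesh_uv_sphere <- function(radius = 1, center = c(0, 0, 0),
                           n_lat = 16, n_lon = 32) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  vid <- function(i, j) (i - 1) * n_lon + ((j - 1) %% n_lon) + 1
  grid <- expand.grid(j = seq_len(n_lon), i = seq_len(n_lat + 1))
  vertices <- cbind(radius * cos(lat[grid$i]) * cos(lon[grid$j]),
                    radius * cos(lat[grid$i]) * sin(lon[grid$j]),
                    radius * sin(lat[grid$i]))
  vertices <- sweep(vertices, 2, as.numeric(center), `+`)
  faces <- NULL
  for (i in seq_len(n_lat)) {
    for (j in seq_len(n_lon)) {
      a <- vid(i, j); b <- vid(i, j + 1)
      c_ <- vid(i + 1, j); d <- vid(i + 1, j + 1)
      faces <- rbind(faces, c(a, b, d), c(a, d, c_))
    }
  }
  triangle_mesh(vertices, faces)
}
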