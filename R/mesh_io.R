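#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Supported dialects: binary and ASCII STL, ASCII PLY (xyz vertex properties,
#' triangular faces), and OBJ (\code{v}/\code{f} records; polygonal faces are
#' fan-triangulated, \code{v/vt/vn} index syntax accepted). STL triangle soups
#' are welded into an indexed mesh by exact coordinate match, vertices ordered
#' by first occurrence. Degenerate faces are dropped with a logged count.
#'
#' @param path file path.
#' @param format one of \code{"stl"}, \code{"ply"}, \code{"obj"}; default
#'   guessed from the file extension.
#' @return a \code{tri_mesh}.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  raw <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop("unsupported mesh format: ", format)
  )
  faces <- drop_degenerate_faces(raw$vertices, raw$faces)
  if (nrow(faces) == 0) stop("no valid faces after dropping degenerate triangles: ", path)
  tri_mesh(raw$vertices, faces)
}

#' Write a triangle mesh
#'
#' @param mesh a \code{tri_mesh}.
#' @param path output path.
#' @param format \code{"stl"} (binary), \code{"stl_ascii"}, \code{"ply"}
#'   (ASCII) or \code{"obj"}; default guessed from the extension.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  validate_tri_mesh(mesh)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
    stl = write_stl_binary(mesh, path),
    stl_ascii = write_stl_ascii(mesh, path),
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format: ", format)
  )
  invisible(path)
}

# ---- STL ----------------------------------------------------------------

is_ascii_stl <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = 512L)
  txt <- rawToChar(head[head != as.raw(0)])
  # byte-wise matching: binary STL headers may hold arbitrary bytes
  grepl("^\\s*solid", txt, useBytes = TRUE) && grepl("facet", txt, useBytes = TRUE)
}

read_stl <- function(path) {
  if (is_ascii_stl(path)) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(n_tri) || n_tri <= 0) stop("unreadable binary STL: ", path)
  body <- readBin(con, "raw", n = n_tri * 50L)
  if (length(body) < n_tri * 50L) stop("truncated binary STL: ", path)
  m <- matrix(body, nrow = 50L)
  coords <- readBin(as.vector(m[1:48, ]), "numeric", n = 12L * n_tri, size = 4L,
                    endian = "little")
  coords <- matrix(coords, nrow = 12L)  # nx ny nz v1 v2 v3 per column
  soup <- t(coords[4:12, , drop = FALSE])  # n_tri x 9
  soup_to_indexed(soup)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) stop("unreadable ASCII STL: ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4])))
  soup <- matrix(t(nums), ncol = 9, byrow = TRUE)
  soup_to_indexed(soup)
}

# Weld a triangle soup (m x 9: v1 v2 v3 coords) into an indexed mesh.
soup_to_indexed <- function(soup) {
  pts <- rbind(soup[, 1:3, drop = FALSE], soup[, 4:6, drop = FALSE], soup[, 7:9, drop = FALSE])
  ord <- c(t(matrix(seq_len(nrow(pts)), ncol = 3)))  # interleave v1,v2,v3 per face
  pts <- pts[ord, , drop = FALSE]
  key <- apply(pts, 1, function(p) paste(format(p, digits = 17), collapse = ","))
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  vertices <- pts[first, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  f <- mesh$faces; v <- mesh$vertices
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  block <- cbind(nrm, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

write_stl_ascii <- function(mesh, path) {
  f <- mesh$faces; v <- mesh$vertices
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid dentseg", con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    n <- crossprod_3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nl <- sqrt(sum(n^2)); if (nl > 0) n <- n / nl
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid dentseg", con)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0 || length(fl) == 0) stop("unreadable OBJ: ", path)
  vertices <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- as.integer(vapply(strsplit(p[-1], "/"), `[[`, "", 1L))
    if (length(idx) < 3) stop("OBJ face with fewer than 3 vertices")
    cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])  # fan triangulation
  }))
  list(vertices = vertices, faces = faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

# ---- PLY (ASCII) --------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") stop("unreadable PLY: ", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY header not terminated: ", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (any(grepl("^format\\s+binary", hdr))) {
    stop("binary PLY is not supported; convert to ASCII PLY, STL or OBJ")
  }
  el <- grep("^element\\s", hdr)
  get_count <- function(name) {
    ln <- hdr[el][grepl(paste0("^element\\s+", name, "\\s"), hdr[el])]
    if (length(ln) != 1) stop("PLY missing element: ", name)
    as.integer(strsplit(ln, "\\s+")[[1]][3])
  }
  nv <- get_count("vertex"); nf <- get_count("face")
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vertices <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(p) {
    k <- as.integer(p[1])
    if (k != 3) stop("non-triangular PLY face")
    as.integer(p[2:4]) + 1L
  }))
  list(vertices = vertices, faces = faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

# ---- label sidecars ------------------------------------------------------

#' Write / read per-face label sidecars
#'
#' Plain-text sidecar: one class code per line, line i labeling face i of the
#' mesh the sidecar accompanies (conventionally \code{<mesh>.labels.txt}).
#' \code{read_labels} also accepts a JSON variant \code{\{"labels": [...]\}}
#' optionally carrying a mesh face-count checksum.
#'
#' @param labels a \code{face_labels} factor.
#' @param path sidecar path.
#' @param mesh the associated \code{tri_mesh}; used to validate length.
#' @return \code{read_labels} returns a \code{face_labels} factor.
#' @export
write_labels <- function(labels, path, mesh = NULL) {
  if (!is.null(mesh) && length(labels) != n_faces(mesh)) {
    stop(sprintf("labeling has %d entries but mesh has %d faces",
                 length(labels), n_faces(mesh)))
  }
  writeLines(as.character(labels), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, mesh = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0 && startsWith(trimws(first), "{")) {
    obj <- jsonlite::fromJSON(path)
    codes <- as.character(obj$labels)
    if (!is.null(obj$n_faces) && !is.null(mesh) && obj$n_faces != n_faces(mesh)) {
      stop("label file checksum does not match mesh face count")
    }
  } else {
    codes <- readLines(path, warn = FALSE)
    codes <- codes[nzchar(codes)]
  }
  face_labels(codes, n_faces = if (is.null(mesh)) NULL else n_faces(mesh))
}
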