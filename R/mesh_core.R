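#' Triangle mesh of a dental arch
#'
#' Minimal mesh container: an \code{n x 3} numeric matrix of vertex positions
#' in millimetres and an \code{m x 3} integer matrix of 1-based vertex
#' indices. No assumptions are made about manifoldness, closedness or
#' orientation. Degenerate faces (repeated vertex index or zero area) are
#' rejected by the validator; readers drop them with a logged count.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per face, 1-based vertex indices.
#' @param validate logical; run invariant checks.
#' @return object of class \code{tri_mesh}.
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- unname(matrix(as.numeric(vertices), ncol = 3))
  faces <- unname(matrix(as.integer(faces), ncol = 3))
  m <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  if (validate) validate_tri_mesh(m)
  m
}

validate_tri_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) < 1) stop("mesh must have at least one face")
  if (anyNA(v) || anyNA(f)) stop("mesh contains NA values")
  if (min(f) < 1 || max(f) > nrow(v)) stop("face indices out of vertex range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop("mesh contains degenerate faces (repeated vertex indices)")
  }
  invisible(mesh)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Face / vertex counts of a mesh
#' @param mesh a \code{tri_mesh}.
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname n_faces
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-face surface areas
#'
#' Half the Euclidean norm of the cross product of two edge vectors of each
#' face, in square millimetres.
#'
#' @param mesh a \code{tri_mesh}.
#' @return numeric vector of non-negative areas, one per face.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  unname(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
}

# Undirected edge table: one row per (face, edge) with canonical vertex order.
face_edge_table <- function(faces) {
  m <- nrow(faces)
  ea <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(ea[, 1], ea[, 2]); hi <- pmax(ea[, 1], ea[, 2])
  data.frame(lo = lo, hi = hi, face = rep.int(seq_len(m), 3L),
             key = lo * (2^26) + hi)
}

#' Edge-adjacency of mesh faces
#'
#' For every face, the faces sharing an undirected edge with it. Symmetric by
#' construction; faces have at most three neighbours on manifold regions,
#' more across non-manifold edges.
#'
#' @param mesh a \code{tri_mesh}.
#' @return list with \code{pairs} (2-column integer matrix of adjacent face
#'   pairs, each unordered pair once) and \code{neighbors} (list of integer
#'   vectors, one per face).
#' @export
face_adjacency <- function(mesh) {
  pairs <- face_adjacency_cpp(mesh$faces, n_vertices(mesh))
  nb <- vector("list", n_faces(mesh))
  if (nrow(pairs) > 0) {
    all_from <- c(pairs[, 1], pairs[, 2])
    all_to <- c(pairs[, 2], pairs[, 1])
    nb_split <- split(all_to, factor(all_from, levels = seq_len(n_faces(mesh))))
    nb <- lapply(nb_split, function(x) sort(unique(x)))
  }
  list(pairs = pairs, neighbors = nb)
}

#' Vertices on the boundary of a labeled region
#'
#' Positions of vertices incident both to a face labeled \code{cls} and to a
#' face with a different label. These label-transition vertex clouds are the
#' point sets compared by the 95th-percentile Hausdorff boundary metric.
#'
#' @param mesh a \code{tri_mesh}.
#' @param labels \code{face_labels} matching the mesh.
#' @param cls a class code.
#' @return numeric matrix (possibly 0-row) of vertex positions.
#' @export
label_boundary_vertices <- function(mesh, labels, cls) {
  stopifnot(length(labels) == n_faces(mesh))
  in_cls <- as.character(labels) == cls
  f <- mesh$faces
  v_in <- unique(as.vector(f[in_cls, , drop = FALSE]))
  v_out <- unique(as.vector(f[!in_cls, , drop = FALSE]))
  vb <- intersect(v_in, v_out)
  mesh$vertices[vb, , drop = FALSE]
}

drop_degenerate_faces <- function(vertices, faces, stage = "read_mesh") {
  rep_idx <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
  keep <- !rep_idx
  if (any(keep)) {
    m <- tri_mesh(vertices, faces[keep, , drop = FALSE], validate = FALSE)
    zero <- face_areas(m) <= 1e-12
    keep[keep] <- !zero
  }
  dropped <- sum(!keep)
  if (dropped > 0) log_msg(stage, "dropped %d degenerate face(s)", dropped, level = "warn")
  faces[keep, , drop = FALSE]
}
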