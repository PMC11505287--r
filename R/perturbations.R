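#' Tessellation perturbations for robustness studies
#'
#' Three geometry/topology modifications used to probe sensitivity to mesh
#' discretization while leaving object semantics intact:
#' \describe{
#'   \item{\code{perturb_rvd}}{random vertex displacement: every vertex moves
#'     along a uniformly random direction by a magnitude drawn uniformly from
#'     \code{[0, max_disp]} mm (default 0.2 mm, the typical error magnitude of
#'     modern intra-oral scanners); topology unchanged.}
#'   \item{\code{perturb_pfo}}{planar flipping optimization: interior manifold
#'     edges are flipped when the flip increases the minimum triangle angle
#'     across the two incident faces (Delaunay-style local quality criterion);
#'     vertex positions unchanged.}
#'   \item{\code{perturb_er}}{explicit isotropic remeshing: iteratively split
#'     edges longer than 4/3 of the target length, collapse edges shorter
#'     than 4/5 of it, flip edges toward valence 6, and tangentially relax
#'     vertices with re-projection onto the input surface.}
#' }
#'
#' @param mesh a \code{tri_mesh}.
#' @param max_disp maximum displacement in mm.
#' @param seed integer RNG seed.
#' @return a perturbed \code{tri_mesh}.
#' @export
perturb_rvd <- function(mesh, max_disp = 0.2, seed = 1L) {
  stopifnot(max_disp >= 0)
  with_seed(seed, {
    n <- n_vertices(mesh)
    dir <- runif_sphere(n)
    mag <- stats::runif(n, 0, max_disp)
    mesh$vertices <- mesh$vertices + dir * mag
  })
  mesh
}

#' @rdname perturb_rvd
#' @param max_passes maximum flip passes.
#' @export
perturb_pfo <- function(mesh, max_passes = 10L) {
  faces <- pfo_flip_cpp(mesh$vertices, mesh$faces - 1L, as.integer(max_passes))
  tri_mesh(mesh$vertices, faces + 1L)
}

#' @rdname perturb_rvd
#' @param target_edge target edge length in mm; default the median input
#'   edge length (pure tessellation change, shape preserved).
#' @param passes remeshing passes.
#' @export
perturb_er <- function(mesh, target_edge = NULL, passes = 4L) {
  if (is.null(target_edge)) target_edge <- stats::median(edge_lengths(mesh))
  stopifnot(target_edge > 0)
  out <- er_remesh_cpp(mesh$vertices, mesh$faces - 1L, target_edge, as.integer(passes))
  if (nrow(out$faces) < 4) stop("remeshing collapsed the mesh below 4 faces")
  # pin the remeshed vertices back onto the input surface
  prj <- point_mesh_project(out$vertices, mesh)
  res <- tri_mesh(prj$point, out$faces + 1L, validate = FALSE)
  res$faces <- drop_degenerate_faces(res$vertices, res$faces, stage = "perturb_er")
  if (nrow(res$faces) < 4) stop("remeshing collapsed the mesh below 4 faces")
  validate_tri_mesh(res)
  res
}

#' Edge lengths of a mesh
#' @param mesh a \code{tri_mesh}.
#' @return numeric vector, one entry per undirected edge.
#' @export
edge_lengths <- function(mesh) {
  et <- face_edge_table(mesh$faces)
  e <- unique(cbind(et$lo, et$hi))
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                mesh$vertices[e[, 2], , drop = FALSE])^2))
}

#' Transport a labeling to a retessellated mesh
#'
#' Assigns each face of \code{new_mesh} the label of the nearest face of
#' \code{mesh} (exact point-to-triangle distance from the new face centroid).
#'
#' @param mesh,labels the labeled source mesh.
#' @param new_mesh the perturbed/remeshed mesh.
#' @return a \code{face_labels} for \code{new_mesh}.
#' @export
transfer_labels_nearest <- function(mesh, labels, new_mesh) {
  prj <- point_mesh_project(face_centroids(new_mesh), mesh)
  face_labels(as.character(labels)[prj$face], n_faces = n_faces(new_mesh))
}

#' Exact nearest point on a mesh surface
#'
#' Grid-accelerated exact point-to-triangle projection of query points onto
#' a triangle mesh.
#'
#' @param points n x 3 query positions.
#' @param mesh a \code{tri_mesh}.
#' @return list with \code{dist} (n distances, mm), \code{face} (1-based
#'   nearest face index) and \code{point} (n x 3 nearest surface positions).
#' @export
point_mesh_project <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  res <- point_mesh_project_cpp(points, mesh$vertices, mesh$faces - 1L)
  list(dist = res$dist, face = res$face + 1L, point = res$point)
}
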