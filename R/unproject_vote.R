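#' Unproject binary mask sequences to mesh faces
#'
#' For every view, each pixel whose mask value is 1 contributes the face its
#' view ray first hit (background pixels contribute nothing). A face hit by
#' any number of pixels within one view counts once for that view, matching
#' the ratio-of-views semantics of the multi-view certainty.
#'
#' @param masks list (or \code{n x H x W} array) of binary masks, one per view.
#' @param records list of render records (with \code{first_hit} and
#'   \code{visible_faces}), aligned with \code{masks}.
#' @param n_faces total face count of the mesh.
#' @return list with \code{faces} (sorted candidate face set), \code{hits}
#'   (integer vector over all faces: number of views whose masked rays first
#'   hit the face) and \code{visible} (number of views in which each face was
#'   visible at all).
#' @export
unproject_masks <- function(masks, records, n_faces) {
  if (is.array(masks) && length(dim(masks)) == 3) {
    masks <- lapply(seq_len(dim(masks)[1]), function(v) masks[v, , ])
  }
  if (length(masks) != length(records)) stop("masks and records length mismatch")
  hits <- integer(n_faces)
  visible <- integer(n_faces)
  for (v in seq_along(masks)) {
    fh <- records[[v]]$first_hit
    if (!all(dim(masks[[v]]) == dim(fh))) stop("mask/record resolution mismatch")
    hit_faces <- unique(fh[masks[[v]] > 0 & fh > 0L])
    hits[hit_faces] <- hits[hit_faces] + 1L
    vis <- records[[v]]$visible_faces
    visible[vis] <- visible[vis] + 1L
  }
  list(faces = which(hits > 0L), hits = hits, visible = visible)
}

#' Multi-view certainty table
#'
#' For each face and tooth class, the certainty is the number of views whose
#' masked rays first hit the face divided by the number of views (of that
#' tooth's own camera trajectory) in which the face was visible at all;
#' faces never visible for a class have certainty 0 for it.
#'
#' @param per_tooth named list (by tooth code) of \code{unproject_masks}
#'   results.
#' @param n_faces total face count.
#' @return object of class \code{certainty_table}: list of \code{hits},
#'   \code{visible} and \code{certainty}, each an \code{n_faces x 16} matrix
#'   with tooth-code columns.
#' @export
build_certainty <- function(per_tooth, n_faces) {
  teeth <- tooth_class_codes(include_gingiva = FALSE)
  hits <- matrix(0L, n_faces, 16, dimnames = list(NULL, teeth))
  visible <- matrix(0L, n_faces, 16, dimnames = list(NULL, teeth))
  for (code in names(per_tooth)) {
    hits[, code] <- per_tooth[[code]]$hits
    visible[, code] <- per_tooth[[code]]$visible
  }
  certainty <- hits / pmax(visible, 1L)
  certainty[visible == 0L] <- 0
  structure(list(hits = hits, visible = visible, certainty = certainty),
            class = "certainty_table")
}

#' @export
print.certainty_table <- function(x, ...) {
  cat(sprintf("<certainty_table> %d faces x %d classes, %d faces claimed\n",
              nrow(x$certainty), ncol(x$certainty), sum(rowSums(x$certainty) > 0)))
  invisible(x)
}

#' Region voting
#'
#' Assigns every face the tooth class with the highest multi-view certainty;
#' ties break to the lower class index, and faces with zero certainty for
#' all classes are gingiva. By construction no face can carry two classes.
#'
#' @param table a \code{certainty_table}.
#' @return a \code{face_labels}.
#' @export
region_voting <- function(table) {
  u <- table$certainty
  best <- max.col(u, ties.method = "first")   # lower class index wins ties
  mx <- u[cbind(seq_len(nrow(u)), best)]
  codes <- colnames(u)[best]
  codes[mx == 0] <- "G"
  face_labels(codes, n_faces = nrow(u))
}

#' Connected-component cleanup
#'
#' Enforces the single-region-per-tooth assumption: for every tooth class
#' whose faces split into several edge-connected components, only the
#' component with the highest face count is kept (ties: larger total area,
#' then lowest face index). Faces of discarded components move to their
#' next-highest-certainty class whose retained region is edge-adjacent to
#' them, else to gingiva. One pass, no iteration.
#'
#' @param mesh a \code{tri_mesh}.
#' @param labeling a \code{face_labels} (typically from
#'   \code{\link{region_voting}}).
#' @param table the \code{certainty_table} used for reassignment.
#' @return a cleaned \code{face_labels}.
#' @export
cca_cleanup <- function(mesh, labeling, table) {
  adj <- face_adjacency(mesh)
  areas <- face_areas(mesh)
  lab <- as.character(labeling)
  teeth <- present_teeth(labeling)
  keep_member <- rep(TRUE, length(lab))
  retained <- list()
  for (cls in teeth) {
    idx <- which(lab == cls)
    comp <- label_components(adj, lab, cls, idx)
    if (max(comp) > 1) {
      score <- vapply(seq_len(max(comp)), function(ci) {
        members <- idx[comp == ci]
        c(length(members), sum(areas[members]), -min(members))
      }, numeric(3))
      best <- order(score[1, ], score[2, ], score[3, ], decreasing = TRUE)[1]
      keep_member[idx[comp != best]] <- FALSE
      retained[[cls]] <- idx[comp == best]
    } else {
      retained[[cls]] <- idx
    }
  }
  discarded <- which(!keep_member)
  out <- lab
  if (length(discarded) > 0) {
    u <- table$certainty
    retained_set <- lapply(retained, function(v) v)
    for (f in discarded) {
      cand <- order(u[f, ], decreasing = TRUE)
      cand <- cand[u[f, cand] > 0]
      cand_codes <- colnames(u)[cand]
      cand_codes <- cand_codes[cand_codes != lab[f]]
      newcls <- "G"
      for (cc in cand_codes) {
        r <- retained_set[[cc]]
        if (!is.null(r) && length(intersect(adj$neighbors[[f]], r)) > 0) {
          newcls <- cc
          break
        }
      }
      out[f] <- newcls
    }
  }
  face_labels(out, n_faces = length(out))
}

# connected components of same-class faces over edge adjacency
label_components <- function(adj, lab, cls, idx) {
  if (length(idx) == 1) return(1L)
  p <- adj$pairs
  sub <- p[lab[p[, 1]] == cls & lab[p[, 2]] == cls, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(sub) > 0) {
    g <- igraph::add_edges(g, as.vector(t(matrix(match(sub, idx), ncol = 2))))
  }
  igraph::components(g)$membership
}
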