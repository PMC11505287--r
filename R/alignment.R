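#' Per-tooth landmark set
#'
#' Sixteen ordered (mesial, distal) surface landmark pairs, one per tooth
#' slot in class-index order \code{L8..L1, R1..R8}. A missing tooth is
#' encoded by \code{Inf} in all six coordinates of its slot.
#'
#' @param m 16 x 6 numeric matrix: columns mesial x,y,z then distal x,y,z.
#' @return object of class \code{landmark_set}.
#' @export
landmark_set <- function(m) {
  m <- matrix(as.numeric(m), ncol = 6)
  if (nrow(m) != 16) stop("a landmark set has exactly 16 tooth slots")
  fin <- is.finite(m)
  both <- rowSums(fin) %in% c(0L, 6L)
  if (!all(both)) stop("mesial and distal landmarks must be both finite or both missing")
  rownames(m) <- tooth_arch_order()
  colnames(m) <- c("mx", "my", "mz", "dx", "dy", "dz")
  structure(m, class = c("landmark_set", "matrix"))
}

#' @export
print.landmark_set <- function(x, ...) {
  pres <- rownames(x)[is.finite(x[, 1])]
  cat(sprintf("<landmark_set> %d/16 teeth present: %s\n", length(pres),
              paste(pres, collapse = " ")))
  invisible(x)
}

landmark_points <- function(lm, teeth = NULL) {
  # stacked 3D points, mesial then distal per present tooth, with slot labels
  keep <- is.finite(lm[, 1])
  if (!is.null(teeth)) keep <- keep & rownames(lm) %in% teeth
  idx <- which(keep)
  pts <- rbind(lm[idx, 1:3, drop = FALSE], lm[idx, 4:6, drop = FALSE])
  ord <- as.vector(rbind(seq_along(idx), seq_along(idx) + length(idx)))
  pts <- pts[ord, , drop = FALSE]
  rownames(pts) <- as.vector(rbind(paste0(rownames(lm)[idx], ".m"),
                                   paste0(rownames(lm)[idx], ".d")))
  pts
}

#' Teeth with finite landmarks
#' @param lm a \code{landmark_set}.
#' @return character vector of tooth codes.
#' @export
landmark_present <- function(lm) rownames(lm)[is.finite(lm[, 1])]

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector in mm.
#' @return object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthogonal")
  }
  if (abs(det(rotation) - 1) > 1e-9) stop("rotation matrix must have det +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Invert a rigid transform
#' @param xf a \code{rigid_transform}.
#' @return the inverse \code{rigid_transform}.
#' @export
invert_transform <- function(xf) {
  rigid_transform(t(xf$rotation), -t(xf$rotation) %*% xf$translation)
}

compose_transform <- function(a, b) {
  # returns the transform applying b first, then a
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Least-squares rigid alignment of landmark sets (occlusion alignment)
#'
#' Solves for the rotation and translation (no scaling) mapping the observed
#' finite landmarks onto the corresponding reference landmarks in the
#' least-squares sense. Correspondence is fixed by tooth slot and
#' mesial/distal role, so the closed-form orthogonal-Procrustes (Kabsch)
#' solution applies directly; no iterative matching is needed, and on exact
#' correspondences the result equals the ICP fixed point. The standard
#' reflection guard flips the smallest singular direction if the optimum has
#' determinant -1.
#'
#' @param observed,reference \code{landmark_set}s; teeth present in both are used.
#' @param refine logical; one trimmed refinement pass dropping point pairs
#'   with residuals above 2.5x the median residual (for noisy landmarks).
#' @return a \code{rigid_transform} mapping observed to reference coordinates.
#' @export
fit_rigid_alignment <- function(observed, reference, refine = FALSE) {
  teeth <- intersect(landmark_present(observed), landmark_present(reference))
  X <- landmark_points(observed, teeth)
  Y <- landmark_points(reference, teeth)
  if (nrow(X) < 4) {
    stop(sprintf("insufficient landmarks: %d finite point pairs, need at least 4", nrow(X)))
  }
  xf <- kabsch(X, Y)
  if (refine) {
    res <- sqrt(rowSums((sweep(X %*% t(xf$rotation), 2, -xf$translation) - Y)^2))
    keep <- res <= 2.5 * stats::median(res)
    if (sum(keep) >= 4 && any(!keep)) xf <- kabsch(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
  }
  xf
}

kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(Xc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    stop("degenerate landmark configuration: points are collinear")
  }
  H <- crossprod(Xc, Yc)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  rigid_transform(R, as.numeric(cy - R %*% cx))
}

#' Apply a rigid transform to a mesh or point matrix
#'
#' Vertices become \code{R v + t}; the face table is untouched.
#'
#' @param mesh a \code{tri_mesh} (or an n x 3 point matrix for
#'   \code{transform_points}).
#' @param xf a \code{rigid_transform}.
#' @return transformed object of the same type.
#' @export
apply_transform <- function(mesh, xf) {
  mesh$vertices <- transform_points(mesh$vertices, xf)
  mesh
}

#' @rdname apply_transform
#' @param points n x 3 numeric matrix.
#' @export
transform_points <- function(points, xf) {
  sweep(points %*% t(xf$rotation), 2, -xf$translation)
}

#' Apply a rigid transform to a landmark set (missing slots stay Inf)
#' @param lm a \code{landmark_set}.
#' @param xf a \code{rigid_transform}.
#' @export
transform_landmarks <- function(lm, xf) {
  out <- unclass(lm)
  fin <- is.finite(out[, 1])
  if (any(fin)) {
    out[fin, 1:3] <- transform_points(out[fin, 1:3, drop = FALSE], xf)
    out[fin, 4:6] <- transform_points(out[fin, 4:6, drop = FALSE], xf)
  }
  landmark_set(out)
}

#' Canonical reference landmark template
#'
#' The shipped full-arch landmark layout defining the canonical coordinate
#' system: upright along +z, centered at the origin in x/y, left and right
#' tooth slots mirror images across the x = 0 plane. Mesial/distal landmarks
#' sit on the occlusal surface height of each crown along the arch tangent.
#'
#' @param arch_width,arch_depth arch parabola size in mm.
#' @param crown_z occlusal landmark height above the gingiva plane in mm.
#' @return a \code{landmark_set} with all 16 teeth present.
#' @export
canonical_reference <- function(arch_width = 64, arch_depth = 56, crown_z = 8) {
  sizes <- tooth_size_table()
  slots <- arch_slots(arch_width, arch_depth, sizes$width)
  m <- matrix(NA_real_, 16, 6)
  # build the right half (slots 9..16 = R1..R8) and mirror for the left
  for (i in 9:16) {
    ctr <- slots$centers[i, ]; tan <- slots$tangents[i, ]
    off <- 0.55 * sizes$width[i] / 2
    mes <- c(ctr - off * tan, crown_z)   # mesial points toward the midline (lower s)
    dis <- c(ctr + off * tan, crown_z)
    m[i, ] <- c(mes, dis)
    mir <- 17 - i                        # mirrored left slot
    m[mir, ] <- c(-mes[1], mes[2], mes[3], -dis[1], dis[2], dis[3])
  }
  # center the template at the origin in x/y (x already symmetric)
  xy_mean <- colMeans(rbind(m[, 1:2], m[, 4:5]))
  m[, c(1, 4)] <- m[, c(1, 4)] - xy_mean[1]
  m[, c(2, 5)] <- m[, c(2, 5)] - xy_mean[2]
  landmark_set(m)
}

#' Write / read landmark sidecars
#'
#' JSON sidecar (\code{<mesh>.landmarks.json}): an array of 16 objects
#' \code{\{"tooth": code, "mesial": [x,y,z], "distal": [x,y,z]\}}; missing
#' teeth are serialized with the string \code{"inf"} in place of coordinates.
#'
#' @param lm a \code{landmark_set}.
#' @param path sidecar path.
#' @export
write_landmarks <- function(lm, path) {
  entries <- lapply(seq_len(16), function(i) {
    if (is.finite(lm[i, 1])) {
      list(tooth = rownames(lm)[i], mesial = unname(lm[i, 1:3]), distal = unname(lm[i, 4:6]))
    } else {
      list(tooth = rownames(lm)[i], mesial = "inf", distal = "inf")
    }
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(entries) != 16) stop("landmark sidecar must have 16 entries")
  m <- matrix(Inf, 16, 6)
  for (i in seq_len(16)) {
    e <- entries[[i]]
    if (!identical(e$mesial, "inf") && !is.null(e$mesial)) {
      m[i, ] <- c(as.numeric(unlist(e$mesial)), as.numeric(unlist(e$distal)))
    }
  }
  landmark_set(m)
}
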