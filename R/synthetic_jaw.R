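#' Specification of a synthetic dental arch
#'
#' Parameters of the parametric jaw generator: convex-ovoid crowns
#' (superellipsoid caps) placed along a parabolic arch on a corrugated
#' gingiva sheet, composited as a height field and triangulated on a
#' near-equilateral grid. Anomaly knobs emulate orthodontic cases: missing
#' teeth (presence flags), crowding (positional jitter / small arches),
#' rotations about the local vertical, and retention (eruption offset).
#'
#' @param arch_width,arch_depth parabolic arch size in mm.
#' @param present logical vector of 16 presence flags in slot order
#'   \code{L8..L1,R1..R8} (optionally named by tooth code).
#' @param crown_scale per-tooth isotropic crown size factor (length 1 or 16).
#' @param rotation per-tooth rotation about the local vertical, radians.
#' @param jitter per-tooth positional jitter magnitude in mm (displacement
#'   sampled uniformly in \code{[-jitter, jitter]^2} in the arch frame).
#' @param eruption per-tooth eruption offset in mm subtracted from crown
#'   height (retention/infraocclusion).
#' @param gingiva_amp gingiva corrugation amplitude in mm.
#' @param target_edge target mesh edge length in mm.
#' @param ridge_height height of the gingival ridge along the arch, mm.
#' @param crown_height nominal crown height above the crown base, mm.
#' @param band_halfwidth half-width of the meshed band around the arch, mm.
#' @param seed integer; fixes all sampled quantities, generation is
#'   deterministic given the spec.
#' @return object of class \code{jaw_spec}.
#' @export
jaw_spec <- function(arch_width = 64, arch_depth = 56,
                     present = rep(TRUE, 16),
                     crown_scale = 1, rotation = 0, jitter = 0, eruption = 0,
                     gingiva_amp = 0.3, target_edge = 1.0,
                     ridge_height = 2.0, crown_height = 6.5,
                     band_halfwidth = 8.0, seed = 1L) {
  rep16 <- function(x) {
    x <- rep_len(as.numeric(x), 16)
    names(x) <- tooth_arch_order()
    x
  }
  present <- rep_len(as.logical(present), 16)
  names(present) <- tooth_arch_order()
  if (!any(present)) stop("at least one tooth must be present")
  stopifnot(arch_width > 0, arch_depth > 0, target_edge > 0, crown_height > 0)
  structure(list(arch_width = arch_width, arch_depth = arch_depth,
                 present = present, crown_scale = rep16(crown_scale),
                 rotation = rep16(rotation), jitter = rep16(jitter),
                 eruption = rep16(eruption), gingiva_amp = gingiva_amp,
                 target_edge = target_edge, ridge_height = ridge_height,
                 crown_height = crown_height, band_halfwidth = band_halfwidth,
                 seed = as.integer(seed)),
            class = "jaw_spec")
}

#' Generate a synthetic labeled dental arch
#'
#' Builds the height-field composite of gingiva sheet and crown caps over a
#' triangulated band following the arch, labels each face by the surface
#' that attains the height maximum at its centroid, and places mesial/distal
#' landmarks on the occlusal surface of every present crown, offset along
#' the (rotated) arch tangent. The output is already in canonical pose:
#' upright along +z, landmark centroid at the origin in x/y.
#'
#' @param spec a \code{jaw_spec}.
#' @return object of class \code{synthetic_case}: list with \code{mesh}
#'   (\code{tri_mesh}), \code{labels} (\code{face_labels}), \code{landmarks}
#'   (\code{landmark_set}) and the generating \code{spec}.
#' @export
generate_jaw <- function(spec) {
  with_seed(spec$seed, generate_jaw_impl(spec))
}

generate_jaw_impl <- function(spec) {
  sizes <- tooth_size_table()
  widths <- sizes$width * spec$crown_scale
  slots <- arch_slots(spec$arch_width, spec$arch_depth, widths)
  if (slots$gap < -0.5) {
    stop(sprintf("arch too small for crowns: inter-tooth gap %.2f mm", slots$gap))
  }
  # per-tooth placement (jitter sampled in the local tangent/normal frame)
  centers <- slots$centers
  tangents <- slots$tangents
  normals <- cbind(-tangents[, 2], tangents[, 1])
  jit <- matrix(stats::runif(32, -1, 1), 16, 2) * spec$jitter
  centers <- centers + jit[, 1] * tangents + jit[, 2] * normals
  rot <- spec$rotation
  # corrugation phases
  ph <- stats::runif(4, 0, 2 * pi)

  crown_a <- pmax(0.5, widths / 2 - 0.15)
  crown_b <- pmax(0.5, sizes$depth * spec$crown_scale / 2 - 0.25)
  crown_h <- pmax(0.5, spec$crown_height - spec$eruption)
  base_z <- 0.75 * spec$ridge_height

  arch_pts <- cbind(slots$curve$t, slots$curve$y)
  active <- which(spec$present)

  # superellipse radial coordinate of points in tooth k's rotated frame
  crown_s <- function(p, k) {
    u0 <- p[, 1] - centers[k, 1]; v0 <- p[, 2] - centers[k, 2]
    tx <- tangents[k, 1]; ty <- tangents[k, 2]
    u <- u0 * tx + v0 * ty; v <- -u0 * ty + v0 * tx
    cr <- cos(rot[k]); sr <- sin(rot[k])
    ur <- u * cr + v * sr; vr <- -u * sr + v * cr
    m <- 2.5
    ((abs(ur) / crown_a[k])^m + (abs(vr) / crown_b[k])^m)^(1 / m)
  }
  # gingiva: ridge along the arch + corrugation + a gingival cuff hugging
  # every crown base (the gingival margin / interdental papillae): gum
  # tissue covers the cervical part of the anatomical crown and fills the
  # space between neighbouring teeth
  cuff_level <- base_z + 0.35 * pmax(0.5, spec$crown_height - spec$eruption)
  gingiva_z <- function(p) {
    d <- nearest_point_dist_cpp(p, arch_pts)
    g <- spec$ridge_height * exp(-(d / 6)^2) +
      spec$gingiva_amp * (sin(0.9 * p[, 1] + ph[1]) * sin(0.7 * p[, 2] + ph[2]) +
                          0.5 * sin(0.35 * p[, 1] + ph[3]) * cos(0.3 * p[, 2] + ph[4]))
    for (k in active) {
      s <- crown_s(p, k)
      g <- pmax(g, cuff_level[k] * exp(-(pmax(s - 1, 0) / 0.3)^2))
    }
    g
  }
  # paraboloid dome: finite wall slope where the crown meets the gingiva
  crown_z <- function(p, k) {
    s <- crown_s(p, k)
    z <- rep(-Inf, nrow(p))
    ins <- s < 1
    z[ins] <- base_z + crown_h[k] * (1 - s[ins]^2)
    z
  }

  grid <- band_grid(arch_pts, spec$band_halfwidth, spec$target_edge)
  # irregular, scan-like tessellation: jitter the planar vertices and
  # restore triangle quality with min-angle flips before lifting heights
  vxy <- grid$vertices +
    matrix(stats::runif(2 * nrow(grid$vertices), -0.28, 0.28), ncol = 2) *
    spec$target_edge
  flat <- pfo_flip_cpp(cbind(vxy, 0), grid$faces - 1L, 5L) + 1L
  heights <- gingiva_z(vxy)
  for (k in active) heights <- pmax(heights, crown_z(vxy, k))
  mesh <- tri_mesh(cbind(vxy, heights), flat)
  mesh$faces <- drop_degenerate_faces(mesh$vertices, mesh$faces,
                                      stage = "generate_jaw")
  validate_tri_mesh(mesh)

  # face labels from the surface attaining the maximum at the centroid
  cen <- face_centroids(mesh)[, 1:2, drop = FALSE]
  g <- gingiva_z(cen)
  best <- g
  lab <- rep.int(17L, nrow(cen))   # gingiva
  for (k in active) {
    ck <- crown_z(cen, k)
    hit <- ck > best
    best[hit] <- ck[hit]
    lab[hit] <- k
  }
  codes16 <- c(tooth_arch_order(), "G")
  labels <- face_labels(codes16[lab], n_faces = nrow(cen))

  check_tooth_components(mesh, labels, names(spec$present)[active])

  # landmarks on the occlusal surface, offset along the rotated tangent
  lm <- matrix(Inf, 16, 6)
  for (k in active) {
    cr <- cos(rot[k]); sr <- sin(rot[k])
    tk <- c(tangents[k, 1] * cr - tangents[k, 2] * sr,
            tangents[k, 1] * sr + tangents[k, 2] * cr)
    off <- 0.55 * crown_a[k]
    sgn <- if (k <= 8) +1 else -1    # mesial is toward the arch midline
    pm_xy <- centers[k, ] + sgn * off * tk
    pd_xy <- centers[k, ] - sgn * off * tk
    zm <- max(gingiva_z(rbind(pm_xy)), crown_z(rbind(pm_xy), k))
    zd <- max(gingiva_z(rbind(pd_xy)), crown_z(rbind(pd_xy), k))
    prj <- point_mesh_project(rbind(c(pm_xy, zm), c(pd_xy, zd)), mesh)
    lm[k, ] <- c(prj$point[1, ], prj$point[2, ])
  }
  lm <- landmark_set(lm)

  # canonical pose: center landmark cloud at the origin in x/y
  ctr <- colMeans(landmark_points(lm))
  shift <- rigid_transform(diag(3), c(-ctr[1], -ctr[2], 0))
  mesh <- apply_transform(mesh, shift)
  lm <- transform_landmarks(lm, shift)

  # exact labeler for arbitrary points in the case's (shifted) coordinates:
  # re-evaluates the analytic height-field argmax, so retessellated copies
  # of this jaw can be labeled without nearest-face transport noise
  labeler <- function(points_xy) {
    p <- cbind(points_xy[, 1] + ctr[1], points_xy[, 2] + ctr[2])
    best <- gingiva_z(p)
    labv <- rep.int(17L, nrow(p))
    for (k in active) {
      ck <- crown_z(p, k)
      hit <- ck > best
      best[hit] <- ck[hit]
      labv[hit] <- k
    }
    codes16[labv]
  }

  structure(list(mesh = mesh, labels = labels, landmarks = lm, spec = spec,
                 labeler = labeler),
            class = "synthetic_case")
}

#' Exact labels of a synthetic case for a retessellated mesh
#'
#' Re-evaluates the generating height-field argmax of a
#' \code{synthetic_case} at the face centroids of another mesh in the same
#' (canonical) coordinates, e.g. a tessellation-perturbed copy. Unlike
#' \code{\link{transfer_labels_nearest}}, this introduces no transport noise
#' at label boundaries.
#'
#' @param case a \code{synthetic_case}.
#' @param mesh a \code{tri_mesh} in the case's coordinates.
#' @return a \code{face_labels} for \code{mesh}.
#' @export
synthetic_labels <- function(case, mesh) {
  if (is.null(case$labeler)) stop("case carries no generator labeler")
  cen <- face_centroids(mesh)[, 1:2, drop = FALSE]
  face_labels(case$labeler(cen), n_faces = n_faces(mesh))
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %d faces, teeth: %s\n", n_faces(x$mesh),
              paste(present_teeth(x$labels), collapse = " ")))
  invisible(x)
}

check_tooth_components <- function(mesh, labels, expected) {
  comp <- tooth_component_count(mesh, labels)
  missing_faces <- setdiff(expected, names(comp))
  multi <- names(comp)[comp > 1]
  bad <- c(missing_faces, multi)
  if (length(bad) > 0) {
    stop("generated crowns collide or vanish for teeth: ", paste(sort(bad), collapse = ", "))
  }
  invisible(comp)
}

# number of edge-connected components per present tooth class
tooth_component_count <- function(mesh, labels) {
  adj <- face_adjacency(mesh)
  out <- integer(0)
  for (cls in present_teeth(labels)) {
    idx <- which(as.character(labels) == cls)
    sub <- adj$pairs[labels[adj$pairs[, 1]] == cls & labels[adj$pairs[, 2]] == cls, ,
                     drop = FALSE]
    g <- igraph::graph_from_edgelist(matrix(match(sub, idx), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    out[cls] <- igraph::components(g)$no
  }
  out
}

# Near-equilateral triangulated band within band_halfwidth of the arch polyline.
band_grid <- function(arch_pts, band_halfwidth, edge) {
  dy <- edge * sqrt(3) / 2
  xr <- range(arch_pts[, 1]) + c(-1, 1) * (band_halfwidth + edge)
  yr <- range(arch_pts[, 2]) + c(-1, 1) * (band_halfwidth + edge)
  nx <- max(3L, ceiling(diff(xr) / edge) + 1L)
  ny <- max(3L, ceiling(diff(yr) / dy) + 1L)
  ij <- expand.grid(j = seq_len(nx), i = seq_len(ny))
  x <- xr[1] + (ij$j - 1) * edge + ((ij$i - 1) %% 2) * edge / 2
  y <- yr[1] + (ij$i - 1) * dy
  vid <- function(i, j) (i - 1L) * nx + j
  i <- rep(seq_len(ny - 1L), each = nx - 1L)
  j <- rep(seq_len(nx - 1L), times = ny - 1L)
  even <- (i - 1L) %% 2L == 0L   # row shifted? even rows at offset 0, odd at +edge/2
  # two triangles per quad; diagonal orientation follows the row offset parity
  f1 <- cbind(vid(i, j), vid(i, j + 1L), ifelse(even, vid(i + 1L, j), vid(i + 1L, j + 1L)))
  f2 <- cbind(ifelse(even, vid(i, j + 1L), vid(i, j)),
              vid(i + 1L, j + 1L), vid(i + 1L, j))
  faces <- rbind(f1, f2)
  verts <- cbind(x, y)
  keep_v <- nearest_point_dist_cpp(verts, arch_pts) <= band_halfwidth
  keep_f <- keep_v[faces[, 1]] & keep_v[faces[, 2]] & keep_v[faces[, 3]]
  faces <- faces[keep_f, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  list(vertices = verts[used, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3))
}

#' Sample a family of varied jaw specifications
#'
#' Draws jaw specs with the anomaly mix the generator is meant to emulate:
#' occasional missing teeth (third molars most often), mild per-tooth
#' rotations, positional jitter producing crowding contacts, per-tooth size
#' variation and occasional retention.
#'
#' @param n number of specs.
#' @param seed integer RNG seed.
#' @param target_edge mesh resolution passed through to each spec.
#' @return list of \code{jaw_spec}.
#' @export
sample_jaw_specs <- function(n, seed = 1L, target_edge = 1.0) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    pres <- rep(TRUE, 16)
    pres[c(1, 16)] <- stats::runif(2) > 0.35      # third molars often absent
    drop_extra <- stats::runif(14) < 0.04
    pres[2:15][drop_extra] <- FALSE
    if (!any(pres)) pres[9] <- TRUE
    jaw_spec(arch_width = stats::runif(1, 62, 68),
             arch_depth = stats::runif(1, 54, 58),
             present = pres,
             crown_scale = stats::runif(16, 0.92, 1.05),
             rotation = stats::rnorm(16, 0, 0.12),
             jitter = stats::runif(16, 0, 0.6),
             eruption = ifelse(stats::runif(16) < 0.06, stats::runif(16, 0.5, 2), 0),
             gingiva_amp = stats::runif(1, 0.15, 0.4),
             target_edge = target_edge,
             seed = sample.int(.Machine$integer.max, 1))
  }))
}
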