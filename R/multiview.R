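#' Orthographic camera pose
#'
#' @param position camera position, mm.
#' @param look_at point the camera looks at, mm.
#' @param up up hint (unit vector, not parallel to the view direction).
#' @param half_extent orthographic viewport half-width/height, mm.
#' @param depth_range depth normalization range along the view ray, mm.
#' @return object of class \code{camera_pose}.
#' @export
camera_pose <- function(position, look_at, up = c(0, 1, 0),
                        half_extent = 10, depth_range = 40) {
  position <- as.numeric(position); look_at <- as.numeric(look_at)
  stopifnot(half_extent > 0, depth_range > 0)
  view <- look_at - position
  vl <- sqrt(sum(view^2))
  if (vl < 1e-12) stop("camera position and look_at coincide")
  view <- view / vl
  up <- as.numeric(up); up <- up / sqrt(sum(up^2))
  if (abs(sum(up * view)) > 1 - 1e-9) stop("up vector parallel to view direction")
  structure(list(position = position, look_at = look_at, up = up,
                 half_extent = half_extent, depth_range = depth_range),
            class = "camera_pose")
}

# orthonormal camera basis: x right, y up(image), z from scene toward camera
camera_basis <- function(pose) {
  z <- pose$position - pose$look_at
  z <- z / sqrt(sum(z^2))
  x <- c(pose$up[2] * z[3] - pose$up[3] * z[2],
         pose$up[3] * z[1] - pose$up[1] * z[3],
         pose$up[1] * z[2] - pose$up[2] * z[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
  list(x = x, y = y, z = z)
}

#' Spiral next-view sampler around one tooth
#'
#' Camera poses on a sphere of given radius centered at the mean of the
#' tooth's mesial and distal landmarks. Pose 0 sits directly above the
#' center (offset along +z); subsequent poses descend the sphere in a spiral
#' with zenith growing linearly to \code{max_zenith} and azimuth advancing
#' by a constant step (default the golden angle). Every camera looks at the
#' center; all cameras are orthographic.
#'
#' @param landmarks_of_tooth list or 2 x 3 matrix with the mesial and distal
#'   landmark positions; both must be finite.
#' @param n number of views.
#' @param radius camera distance from the view center, mm.
#' @param max_zenith maximum polar angle from +z, radians.
#' @param azimuth_step azimuth increment per view, radians.
#' @param half_extent,depth_range viewport parameters (see
#'   \code{\link{camera_pose}}).
#' @return list of \code{camera_pose} of length \code{n}.
#' @export
sample_views <- function(landmarks_of_tooth, n = 49L, radius = 15,
                         max_zenith = pi / 3, azimuth_step = 2.39996322972865332,
                         half_extent = 10, depth_range = 40) {
  lm <- matrix(as.numeric(unlist(landmarks_of_tooth)), ncol = 3, byrow = FALSE)
  if (is.list(landmarks_of_tooth)) {
    lm <- rbind(as.numeric(landmarks_of_tooth[[1]]), as.numeric(landmarks_of_tooth[[2]]))
  }
  if (!all(is.finite(lm))) stop("missing tooth: landmarks are not finite")
  stopifnot(n >= 1)
  ctr <- colMeans(lm)
  lapply(seq_len(n) - 1L, function(i) {
    theta <- if (n == 1L) 0 else max_zenith * i / (n - 1)
    phi <- i * azimuth_step
    pos <- ctr + radius * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    view <- ctr - pos
    up <- c(0, 1, 0)
    if (abs(sum(up * view / sqrt(sum(view^2)))) > 1 - 1e-9) up <- c(1, 0, 0)
    camera_pose(pos, ctr, up, half_extent, depth_range)
  })
}

#' Render one orthographic view
#'
#' One view ray per pixel center; the nearest intersected triangle defines
#' the pixel. Depth is encoded as \code{1 - t/depth_range} clipped to
#' (0, 1] (nearer is larger, 0 means no hit); normals are per-face (flat
#' shading) rotated into camera coordinates and oriented toward the camera;
#' the background normal is the zero vector. Image row 1 is the top of the
#' viewport (+up).
#'
#' @param mesh a \code{tri_mesh}.
#' @param pose a \code{camera_pose}.
#' @param resolution image height = width in pixels.
#' @return list with \code{maps} (list: \code{depth} HxW in [0,1],
#'   \code{normal} HxWx3 in [-1,1]) and \code{record} (list:
#'   \code{first_hit} HxW integer, 0 on background; \code{visible_faces}
#'   sorted integer vector).
#' @export
render_view <- function(mesh, pose, resolution = 256L) {
  basis <- camera_basis(pose)
  res <- render_raster_cpp(mesh$vertices, mesh$faces - 1L,
                           pose$position, basis$x, basis$y, basis$z,
                           pose$half_extent, pose$depth_range,
                           as.integer(resolution), as.integer(resolution))
  list(maps = list(depth = res$depth, normal = res$normal),
       record = list(first_hit = res$first_hit, visible_faces = res$visible_faces),
       pose = pose)
}

#' Render an ordered sequence of views
#'
#' @param mesh a \code{tri_mesh}.
#' @param poses list of \code{camera_pose} (e.g. from
#'   \code{\link{sample_views}}).
#' @param resolution image size in pixels.
#' @return object of class \code{view_sequence}: list of render results in
#'   pose order.
#' @export
render_sequence <- function(mesh, poses, resolution = 256L) {
  structure(lapply(poses, function(p) render_view(mesh, p, resolution)),
            class = "view_sequence")
}

#' @export
print.view_sequence <- function(x, ...) {
  hw <- dim(x[[1]]$maps$depth)
  cat(sprintf("<view_sequence> %d views, %dx%d\n", length(x), hw[1], hw[2]))
  invisible(x)
}

#' Stack a rendered sequence into network input
#'
#' Concatenates depth, the three normal channels, and a constant tooth-type
#' channel into the \code{n x 5 x H x W} array consumed by the segmentation
#' network.
#'
#' @param views a \code{view_sequence}.
#' @param i_tt tooth-type scalar in (0, 1] (see
#'   \code{\link{tooth_type_signal}}).
#' @return numeric array \code{n x 5 x H x W}.
#' @export
sequence_input <- function(views, i_tt) {
  H <- nrow(views[[1]]$maps$depth); W <- ncol(views[[1]]$maps$depth)
  n <- length(views)
  x <- array(0, dim = c(n, 5L, H, W))
  for (v in seq_len(n)) {
    x[v, 1, , ] <- views[[v]]$maps$depth
    x[v, 2:4, , ] <- aperm(views[[v]]$maps$normal, c(3, 1, 2))
    x[v, 5, , ] <- i_tt
  }
  x
}

#' Dump rendered maps as PNG images (debug aid)
#'
#' Writes the depth map as a 16-bit grayscale PNG and the normal map as an
#' 8-bit RGB PNG (components remapped from [-1, 1] to [0, 255]).
#'
#' @param view a single render result from \code{\link{render_view}}.
#' @param prefix output path prefix; writes \code{<prefix>_depth.png} and
#'   \code{<prefix>_normal.png}.
#' @export
write_view_maps <- function(view, prefix) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for map dumps")
  }
  png::writePNG(view$maps$depth, paste0(prefix, "_depth.png"))
  png::writePNG((view$maps$normal + 1) / 2, paste0(prefix, "_normal.png"))
  invisible(prefix)
}
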