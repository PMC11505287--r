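# Shared fixtures, all built in code.

# two coplanar triangles forming the unit square in z = 0
quad_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

# closed unit cube (12 faces)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  tri_mesh(v, f)
}

# regular grid of triangles in the z = 0 plane over [0, nx] x [0, ny]
plane_grid_mesh <- function(nx = 4, ny = 4) {
  v <- as.matrix(expand.grid(x = 0:nx, y = 0:ny))
  v <- cbind(v, 0)
  vid <- function(i, j) i + (nx + 1) * j + 1
  f <- NULL
  for (j in 0:(ny - 1)) {
    for (i in 0:(nx - 1)) {
      f <- rbind(f, c(vid(i, j), vid(i + 1, j), vid(i, j + 1)),
                 c(vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1)))
    }
  }
  tri_mesh(v, f)
}

# latitude/longitude sphere mesh
sphere_mesh <- function(radius = 8, n_lat = 24, n_lon = 36) {
  th <- seq(0, pi, length.out = n_lat + 1)[-c(1, n_lat + 1)]
  ph <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  ring <- function(t) cbind(radius * sin(t) * cos(ph), radius * sin(t) * sin(ph),
                            radius * cos(t))
  v <- rbind(c(0, 0, radius), do.call(rbind, lapply(th, ring)), c(0, 0, -radius))
  np <- 1L
  f <- NULL
  idx <- function(i, j) np + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  for (j in seq_len(n_lon)) f <- rbind(f, c(1L, idx(1, j), idx(1, j + 1)))
  for (i in seq_len(length(th) - 1)) {
    for (j in seq_len(n_lon)) {
      f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                 c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  bot <- np + length(th) * n_lon + 1L
  for (j in seq_len(n_lon)) f <- rbind(f, c(bot, idx(length(th), j + 1), idx(length(th), j)))
  tri_mesh(v, f)
}

# small cached synthetic jaw shared across test files
small_jaw <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_jaw(jaw_spec(seed = 7L, target_edge = 1.2))
    cache
  }
})

random_labels <- function(n, seed = 1) {
  withr::with_seed(seed, face_labels(sample(tooth_class_codes(), n, replace = TRUE)))
}

# brute-force first-hit orthographic ray caster (independent oracle for the
# rasterizing renderer); matches its near-tie rule (lower face index wins
# within 1e-5 along the ray)
rayclast_oracle <- function(mesh, pose, resolution) {
  b <- dentseg:::camera_basis(pose)
  he <- pose$half_extent
  H <- resolution; W <- resolution
  first <- matrix(0L, H, W)
  tbuf <- matrix(Inf, H, W)
  v <- mesh$vertices; f <- mesh$faces
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      px <- -he + (cc - 0.5) / W * 2 * he
      py <- he - (r - 0.5) / H * 2 * he
      o <- pose$position + px * b$x + py * b$y
      d <- -b$z
      for (fi in seq_len(nrow(f))) {
        tri <- v[f[fi, ], ]
        e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
        pvec <- c(d[2] * e2[3] - d[3] * e2[2], d[3] * e2[1] - d[1] * e2[3],
                  d[1] * e2[2] - d[2] * e2[1])
        det <- sum(e1 * pvec)
        if (abs(det) < 1e-12) next
        tvec <- o - tri[1, ]
        u <- sum(tvec * pvec) / det
        if (u < 0 || u > 1) next
        qvec <- c(tvec[2] * e1[3] - tvec[3] * e1[2], tvec[3] * e1[1] - tvec[1] * e1[3],
                  tvec[1] * e1[2] - tvec[2] * e1[1])
        w <- sum(d * qvec) / det
        if (w < 0 || u + w > 1) next
        t <- sum(e2 * qvec) / det
        if (t <= 0) next
        if (t < tbuf[r, cc] - 1e-5) {
          tbuf[r, cc] <- t
          first[r, cc] <- fi
        }
      }
    }
  }
  first
}

# binary dilation with a (2k+1)x(2k+1) square structuring element
dilate_mask <- function(m, k = 1L) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (dr in -k:k) {
    rs <- max(1, 1 + dr):min(H, H + dr)
    rd <- max(1, 1 - dr):min(H, H - dr)
    for (dc in -k:k) {
      cs <- max(1, 1 + dc):min(W, W + dc)
      cd <- max(1, 1 - dc):min(W, W - dc)
      out[rd, cd] <- pmax(out[rd, cd], m[rs, cs])
    }
  }
  out
}

# brute-force nearest-neighbour distances (metric oracle building block)
nnd_oracle <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    min(vapply(seq_len(nrow(B)), function(j) sqrt(sum((A[i, ] - B[j, ])^2)),
               numeric(1)))
  }, numeric(1))
}
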