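test_that("spiral view sampler geometry", {
  lm <- list(c(1, 2, 3), c(2, 2, 3))
  poses <- sample_views(lm, n = 49L, radius = 15)
  expect_length(poses, 49)
  ctr <- c(1.5, 2, 3)
  expect_equal(poses[[1]]$position, ctr + c(0, 0, 15), tolerance = 1e-12)
  for (p in poses) {
    expect_equal(sqrt(sum((p$position - ctr)^2)), 15, tolerance = 1e-9)
    expect_equal(p$look_at, ctr, tolerance = 1e-12)
  }
  # zenith grows linearly to the maximum
  zen <- vapply(poses, function(p) {
    d <- p$position - ctr
    acos(d[3] / sqrt(sum(d^2)))
  }, numeric(1))
  expect_equal(zen, pi / 3 * (0:48) / 48, tolerance = 1e-9)
  expect_error(sample_views(list(c(Inf, Inf, Inf), c(Inf, Inf, Inf))), "missing tooth")
})

test_that("rendering a large perpendicular plane gives uniform depth and normals", {
  m <- tri_mesh(rbind(c(-50, -50, 0), c(50, -50, 0), c(50, 50, 0), c(-50, 50, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
  pose <- camera_pose(c(0, 0, 15), c(0, 0, 0), half_extent = 10, depth_range = 40)
  rv <- render_view(m, pose, 32L)
  expect_true(all(rv$maps$depth == 1 - 15 / 40))
  expect_true(all(rv$maps$normal[, , 3] == 1))
  expect_true(all(rv$maps$normal[, , 1:2] == 0))
  expect_setequal(rv$record$visible_faces, 1:2)
})

test_that("empty frustum renders all-background maps", {
  m <- tri_mesh(rbind(c(100, 100, 0), c(101, 100, 0), c(100, 101, 0)),
                rbind(c(1, 2, 3)))
  pose <- camera_pose(c(0, 0, 15), c(0, 0, 0))
  rv <- render_view(m, pose, 16L)
  expect_true(all(rv$maps$depth == 0))
  expect_true(all(rv$maps$normal == 0))
  expect_length(rv$record$visible_faces, 0)
  expect_true(all(rv$record$first_hit == 0))
})

test_that("occluded geometry never reaches the first-hit buffer", {
  # two stacked squares; the rear one is fully hidden
  v <- rbind(c(-5, -5, 5), c(5, -5, 5), c(5, 5, 5), c(-5, 5, 5),
             c(-4, -4, 0), c(4, -4, 0), c(4, 4, 0), c(-4, 4, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(5, 6, 7), c(5, 7, 8))
  m <- tri_mesh(v, f)
  pose <- camera_pose(c(0, 0, 20), c(0, 0, 0), half_extent = 6, depth_range = 40)
  rv <- render_view(m, pose, 64L)
  expect_true(all(rv$record$visible_faces %in% 1:2))
  masks <- array(1L, dim = c(1, 64, 64))
  up <- unproject_masks(masks, list(rv$record), n_faces(m))
  expect_true(all(up$faces %in% 1:2))
})

test_that("depth/normal background consistency holds on rendered jaws", {
  jaw <- small_jaw()
  poses <- sample_views(list(jaw$landmarks["L3", 1:3], jaw$landmarks["L3", 4:6]),
                        n = 5)
  views <- render_sequence(jaw$mesh, poses, 64L)
  expect_length(views, 5)
  for (rv in views) {
    bg <- rv$maps$depth == 0
    nl <- sqrt(rv$maps$normal[, , 1]^2 + rv$maps$normal[, , 2]^2 +
               rv$maps$normal[, , 3]^2)
    expect_true(all(nl[bg] == 0))
    expect_true(all(abs(nl[!bg] - 1) < 1e-3))
    expect_true(all(rv$maps$normal[, , 3][!bg] >= 0))
    expect_setequal(rv$record$visible_faces,
                    unique(rv$record$first_hit[rv$record$first_hit > 0]))
    expect_true(all((rv$record$first_hit == 0) == bg))
  }
  # determinism
  views2 <- render_sequence(jaw$mesh, poses, 64L)
  expect_identical(views[[3]]$maps$depth, views2[[3]]$maps$depth)
})

test_that("rasterizer matches the brute-force ray-casting oracle", {
  set.seed(21)
  # small random triangle clouds and a structured fixture
  fixtures <- list(
    tri_mesh(matrix(runif(3 * 30, -8, 8), ncol = 3), matrix(sample(30, 30), ncol = 3)),
    cube_mesh()
  )
  fixtures[[2]]$vertices <- fixtures[[2]]$vertices * 6 - 3
  poses <- list(
    camera_pose(c(0, 0, 20), c(0, 0, 0), half_extent = 9),
    camera_pose(c(12, 9, 14), c(0, 0, 0), half_extent = 9)
  )
  for (m in fixtures) {
    for (pose in poses) {
      rv <- render_view(m, pose, 24L)
      oracle <- rayclast_oracle(m, pose, 24L)
      expect_equal(sum(rv$record$first_hit != oracle), 0)
    }
  }
})

test_that("49 views cover essentially all faces of a tooth", {
  jaw <- small_jaw()
  tooth <- "R6"
  poses <- sample_views(list(jaw$landmarks[tooth, 1:3], jaw$landmarks[tooth, 4:6]),
                        n = 49L)
  views <- render_sequence(jaw$mesh, poses, 256L)
  vis <- sort(unique(unlist(lapply(views, function(v) v$record$visible_faces))))
  tooth_faces <- which(as.character(jaw$labels) == tooth)
  expect_gte(mean(tooth_faces %in% vis), 0.99)
})

test_that("visible faces are resolution-monotone on a convex fixture", {
  m <- sphere_mesh(radius = 6, n_lat = 12, n_lon = 18)
  pose <- camera_pose(c(0, 0, 15), c(0, 0, 0), half_extent = 8, depth_range = 40)
  v64 <- render_view(m, pose, 64L)$record$visible_faces
  v256 <- render_view(m, pose, 256L)$record$visible_faces
  expect_true(all(v64 %in% v256))
})

test_that("sequence input stacking carries the constant tooth-type channel", {
  jaw <- small_jaw()
  poses <- sample_views(list(jaw$landmarks["R1", 1:3], jaw$landmarks["R1", 4:6]), n = 3)
  views <- render_sequence(jaw$mesh, poses, 32L)
  x <- sequence_input(views, 0.5625)
  expect_equal(dim(x), c(3, 5, 32, 32))
  expect_true(all(x[, 5, , ] == 0.5625))
  expect_equal(x[2, 1, , ], views[[2]]$maps$depth)
  expect_equal(x[2, 3, , ], views[[2]]$maps$normal[, , 2])
})
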