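test_that("dice loss closed forms", {
  ones4 <- matrix(1, 2, 2)
  zeros4 <- matrix(0, 2, 2)
  expect_equal(dice_loss(ones4, ones4, eps = 1), 1 - 9 / 9)
  expect_equal(dice_loss(zeros4, ones4, eps = 1), 1 - 1 / 5)
  half <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_loss(ones4, half, eps = 1e-12), 1 / 3, tolerance = 1e-9)
  expect_error(dice_loss(ones4, matrix(1, 3, 3)), "shapes differ")
})

test_that("dice gradient matches numerical differentiation to 1e-4", {
  set.seed(2)
  for (rep in 1:5) {
    p <- matrix(runif(16), 4, 4)
    r <- matrix(rbinom(16, 1, 0.5), 4, 4)
    eps <- runif(1, 0.5, 2)
    g <- dice_loss_grad(p, r, eps)
    h <- 1e-6
    for (idx in sample(16, 4)) {
      pp <- p; pp[idx] <- pp[idx] + h
      pm <- p; pm[idx] <- pm[idx] - h
      num <- (dice_loss(pp, r, eps) - dice_loss(pm, r, eps)) / (2 * h)
      expect_equal(g[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("deep-supervised loss sums per-stage dice terms", {
  set.seed(3)
  ref <- matrix(rbinom(64, 1, 0.4), 8, 8)
  full <- matrix(runif(64), 8, 8)
  expect_equal(deep_supervised_loss(list(full), ref), dice_loss(full, ref))
  # per-term oracle: nearest-neighbour downsampled references
  half <- matrix(runif(16), 4, 4)
  got <- deep_supervised_loss(list(half, full), ref)
  ref_half <- ref[seq(1, 8, by = 2), seq(1, 8, by = 2)]
  expect_equal(got, dice_loss(half, ref_half) + dice_loss(full, ref))
  # identical perfect predictions at every head give zero at eps -> 0
  exact <- list(ref_half, ref)
  expect_equal(deep_supervised_loss(exact, ref, eps = 1e-9), 0, tolerance = 1e-6)
})

test_that("augmentation transforms stay in range and act as similarities", {
  angs <- numeric(0); trs <- NULL; scs <- numeric(0)
  for (seed in 1:200) {
    xf <- sample_augment(seed)
    angs <- c(angs, xf$angle); trs <- rbind(trs, xf$translation)
    scs <- c(scs, xf$scale)
  }
  expect_true(all(angs >= -pi / 4 & angs <= pi / 4))
  expect_true(all(trs >= -5 & trs <= 5))
  expect_true(all(scs >= 0.8 & scs <= 1.2))

  jaw <- small_jaw()
  ident <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          scale = 1, angle = 0, axis = c(0, 0, 1)),
                     class = "augment_transform")
  expect_equal(augment_mesh(jaw$mesh, ident)$vertices, jaw$mesh$vertices)
  xf <- sample_augment(4)
  aug <- augment_case(jaw, xf)
  expect_identical(aug$mesh$faces, jaw$mesh$faces)
  expect_identical(as.character(aug$labels), as.character(jaw$labels))
  idx <- seq(1, n_vertices(jaw$mesh), by = 71)
  expect_equal(as.numeric(dist(aug$mesh$vertices[idx, ])),
               xf$scale * as.numeric(dist(jaw$mesh$vertices[idx, ])),
               tolerance = 1e-9)
  # landmarks move with the mesh surface
  pts <- dentseg:::landmark_points(aug$landmarks)
  expect_lt(max(point_mesh_project(pts, aug$mesh)$dist), 0.1 * xf$scale + 1e-9)
})

test_that("targets mark exactly the tooth's first-hit pixels", {
  jaw <- small_jaw()
  poses <- sample_views(list(jaw$landmarks["L5", 1:3], jaw$landmarks["L5", 4:6]), n = 4)
  views <- render_sequence(jaw$mesh, poses, 64L)
  tg <- make_targets(jaw$labels, "L5", views)
  expect_equal(dim(tg), c(4, 64, 64))
  for (v in 1:4) {
    fh <- views[[v]]$record$first_hit
    expect_true(all(tg[v, , ][fh == 0] == 0))      # background never positive
    hit <- fh > 0
    expect_equal(tg[v, , ][hit],
                 as.integer(as.character(jaw$labels)[fh[hit]] == "L5"))
  }
  # unprojecting the targets returns exactly the tooth's visible faces
  up <- unproject_masks(tg, lapply(views, `[[`, "record"), n_faces(jaw$mesh))
  vis <- sort(unique(unlist(lapply(views, function(v) v$record$visible_faces))))
  tooth_faces <- which(as.character(jaw$labels) == "L5")
  expect_setequal(up$faces, intersect(vis, tooth_faces))
  expect_error(make_targets(jaw$labels, "G", views), "absent|no tooth")
})

test_that("cosine annealing restarts span the learning-rate range", {
  lr <- vapply(1:20, dentseg:::cosine_lr, numeric(1), base_lr = 0.01, period = 10)
  expect_equal(lr[1], 0.01)
  expect_lt(lr[10], 1e-3)
  expect_equal(lr[11], 0.01)                 # warm restart
  expect_true(all(diff(lr[1:10]) < 0))
})

test_that("short training run splits 4:1, logs losses and reduces them", {
  specs <- sample_jaw_specs(5, seed = 31L, target_edge = 1.5)
  cases <- lapply(specs, generate_jaw)
  net_cfg <- network_config(stage_widths = c(4, 8), recurrent_hidden = 4L,
                            resolution = 32L)
  tr_cfg <- train_config(batch_size = 2L, iterations = 30L, n_views = 3L,
                         learning_rate = 0.01, resolution = 32L,
                         restart_period = 30L, n_augment = 1L, eval_every = 10L,
                         seed = 3L, epsilon = 1.0)
  fit <- train(cases, net_cfg, tr_cfg, verbose = FALSE)
  expect_length(fit$split$val, 1)
  expect_length(fit$split$train, 4)
  expect_length(intersect(fit$split$train, fit$split$val), 0)
  expect_equal(nrow(fit$log), 30)
  expect_true(all(is.finite(fit$log$loss)))
  # loss decreases over the run (median of halves)
  expect_lt(median(fit$log$loss[16:30]), median(fit$log$loss[1:15]))
  expect_true(is.finite(fit$best_val))
})

test_that("training is reproducible under a fixed seed", {
  specs <- sample_jaw_specs(3, seed = 17L, target_edge = 1.6)
  cases <- lapply(specs, generate_jaw)
  net_cfg <- network_config(stage_widths = c(4, 8), recurrent_hidden = 2L,
                            resolution = 32L)
  tr_cfg <- train_config(batch_size = 1L, iterations = 6L, n_views = 3L,
                         resolution = 32L, n_augment = 0L, eval_every = 6L,
                         seed = 12L)
  f1 <- train(cases, net_cfg, tr_cfg, verbose = FALSE)
  f2 <- train(cases, net_cfg, tr_cfg, verbose = FALSE)
  expect_equal(f1$log$loss, f2$log$loss, tolerance = 1e-6)
  expect_identical(f1$split, f2$split)
})
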