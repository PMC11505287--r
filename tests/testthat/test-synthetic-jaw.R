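test_that("generation is deterministic and respects presence flags", {
  pres <- rep(TRUE, 16)
  pres[c(1, 16)] <- FALSE          # no third molars: 14 teeth
  spec <- jaw_spec(present = pres, seed = 11L, target_edge = 1.3)
  a <- generate_jaw(spec)
  b <- generate_jaw(spec)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(as.character(a$labels), as.character(b$labels))
  expect_length(present_teeth(a$labels), 14)
  expect_false(any(c("L8", "R8") %in% present_teeth(a$labels)))
  expect_setequal(landmark_present(a$landmarks), present_teeth(a$labels))
})

test_that("every landmark lies on the mesh surface", {
  jaw <- small_jaw()
  pts <- dentseg:::landmark_points(jaw$landmarks)
  prj <- point_mesh_project(pts, jaw$mesh)
  expect_lt(max(prj$dist), 0.1)
})

test_that("each present tooth forms exactly one connected component", {
  for (seed in c(7L, 23L)) {
    jaw <- generate_jaw(jaw_spec(seed = seed, target_edge = 1.3,
                                 jitter = 0.3, rotation = 0.1))
    comp <- dentseg:::tooth_component_count(jaw$mesh, jaw$labels)
    expect_true(all(comp == 1))
  }
})

test_that("positional jitter raises crowding contacts on average", {
  contacts <- function(jaw) {
    adj <- face_adjacency(jaw$mesh)
    l <- as.character(jaw$labels)
    p <- adj$pairs
    sum(l[p[, 1]] != l[p[, 2]] & l[p[, 1]] != "G" & l[p[, 2]] != "G")
  }
  lo <- hi <- numeric(0)
  for (seed in 1:6) {
    lo <- c(lo, contacts(generate_jaw(jaw_spec(seed = seed, jitter = 0,
                                               target_edge = 1.3))))
    hi <- c(hi, contacts(generate_jaw(jaw_spec(seed = seed, jitter = 1.2,
                                               target_edge = 1.3))))
  }
  expect_gt(mean(hi), mean(lo))
})

test_that("random vertex displacement stays within bounds, topology fixed", {
  jaw <- small_jaw()
  p0 <- perturb_rvd(jaw$mesh, max_disp = 0, seed = 5)
  expect_equal(p0$vertices, jaw$mesh$vertices)
  p <- perturb_rvd(jaw$mesh, max_disp = 0.2, seed = 5)
  expect_identical(p$faces, jaw$mesh$faces)
  disp <- sqrt(rowSums((p$vertices - jaw$mesh$vertices)^2))
  expect_lte(max(disp), 0.2 + 1e-12)
  expect_gt(mean(disp), 0.05)      # displacements actually drawn
  # deterministic under the seed
  expect_identical(perturb_rvd(jaw$mesh, 0.2, seed = 5)$vertices, p$vertices)
})

test_that("planar flipping optimization improves angles, keeps vertices", {
  # an equilateral-style grid is already optimal: no flips
  pg <- small_jaw()$mesh
  min_angles <- function(m) {
    v <- m$vertices; f <- m$faces
    vapply(seq_len(nrow(f)), function(fi) {
      tri <- v[f[fi, ], ]
      e <- c(sqrt(sum((tri[1, ] - tri[2, ])^2)), sqrt(sum((tri[2, ] - tri[3, ])^2)),
             sqrt(sum((tri[3, ] - tri[1, ])^2)))
      s <- sort(e)
      acos(pmin(1, pmax(-1, (s[2]^2 + s[3]^2 - s[1]^2) / (2 * s[2] * s[3]))))
    }, numeric(1))
  }
  # planar quad split along the long diagonal flips to the short one
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(3, 2, 0), c(1, 2, 0))
  m <- tri_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))   # long diagonal 1-3
  out <- perturb_pfo(m)
  expect_identical(out$vertices, m$vertices)
  edges_of <- function(mm) {
    et <- dentseg:::face_edge_table(mm$faces)
    unique(paste(et$lo, et$hi))
  }
  expect_true("2 4" %in% edges_of(out))      # short diagonal present
  expect_false("1 3" %in% edges_of(out))     # long diagonal flipped away
  expect_gt(min(min_angles(out)), min(min_angles(m)))
  # fixed point: flipping again changes nothing
  out2 <- perturb_pfo(out)
  expect_identical(out2$faces, out$faces)
})

test_that("isotropic remeshing hits the target edge length and preserves shape", {
  sp <- sphere_mesh(radius = 8, n_lat = 16, n_lon = 24)
  target <- 2.0
  out <- perturb_er(sp, target_edge = target, passes = 4)
  med <- median(edge_lengths(out))
  expect_gt(med, 0.7 * target)
  expect_lt(med, 1.3 * target)
  # area change below 2%
  expect_lt(abs(sum(face_areas(out)) - sum(face_areas(sp))) / sum(face_areas(sp)),
            0.02)
  # surface fidelity: sampled points of each mesh near the other surface
  d1 <- point_mesh_project(out$vertices, sp)$dist
  cen <- (out$vertices[out$faces[, 1], ] + out$vertices[out$faces[, 2], ] +
          out$vertices[out$faces[, 3], ]) / 3
  d2 <- point_mesh_project(cen, sp)$dist
  expect_lte(max(quantile(c(d1, d2), 0.95)), 0.1)
})

test_that("remeshed jaw stays within 0.1 mm of the input surface", {
  jaw <- small_jaw()
  out <- perturb_er(jaw$mesh)
  samp <- rbind(out$vertices[seq(1, n_vertices(out), by = 3), ])
  d <- point_mesh_project(samp, jaw$mesh)$dist
  expect_lte(unname(quantile(d, 0.95)), 0.1)
  # label transport is defined for every face
  lab <- transfer_labels_nearest(jaw$mesh, jaw$labels, out)
  expect_length(lab, n_faces(out))
  expect_gte(length(present_teeth(lab)), 15)
})

test_that("perturbed meshes keep a transportable labeling", {
  jaw <- small_jaw()
  for (pm in list(perturb_rvd(jaw$mesh, 0.2, seed = 2), perturb_pfo(jaw$mesh))) {
    lab <- transfer_labels_nearest(jaw$mesh, jaw$labels, pm)
    # same teeth present, similar face shares
    expect_setequal(present_teeth(lab), present_teeth(jaw$labels))
    frac0 <- mean(as.character(jaw$labels) != "G")
    frac1 <- mean(as.character(lab) != "G")
    expect_lt(abs(frac0 - frac1), 0.05)
  }
})

test_that("overlapping crowns that merge classes raise a generation error", {
  spec <- jaw_spec(seed = 3L, target_edge = 1.3)
  spec$jitter[] <- 0
  # slam two incisors onto the same spot via extreme crown scale
  spec$crown_scale[8:9] <- 2.6
  expect_error(generate_jaw(spec), "collide|gap")
})

test_that("sampled jaw spec families generate valid varied cases", {
  specs <- sample_jaw_specs(3, seed = 9L, target_edge = 1.4)
  cases <- lapply(specs, generate_jaw)
  counts <- vapply(cases, function(cs) length(present_teeth(cs$labels)), numeric(1))
  expect_true(all(counts >= 10))
  expect_true(all(vapply(cases, function(cs) {
    all(dentseg:::tooth_component_count(cs$mesh, cs$labels) == 1)
  }, logical(1))))
})
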