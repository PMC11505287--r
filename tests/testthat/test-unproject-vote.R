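# exhaustive per-pixel brute-force reimplementation of the unproject ->
# certainty -> vote path, used as an oracle on tiny scenes
vote_oracle <- function(mesh, per_tooth_views_masks, n_views) {
  nf <- n_faces(mesh)
  teeth <- names(per_tooth_views_masks)
  cert <- matrix(0, nf, length(teeth), dimnames = list(NULL, teeth))
  for (tooth in teeth) {
    vm <- per_tooth_views_masks[[tooth]]
    hits <- integer(nf); vis <- integer(nf)
    for (v in seq_along(vm$views)) {
      fh <- vm$views[[v]]$record$first_hit
      seen <- rep(FALSE, nf); hit <- rep(FALSE, nf)
      for (r in seq_len(nrow(fh))) {
        for (cc in seq_len(ncol(fh))) {
          fi <- fh[r, cc]
          if (fi > 0) {
            seen[fi] <- TRUE
            if (vm$masks[v, r, cc] == 1) hit[fi] <- TRUE
          }
        }
      }
      vis <- vis + seen
      hits <- hits + hit
    }
    cert[, tooth] <- ifelse(vis > 0, hits / vis, 0)
  }
  codes <- character(nf)
  for (fi in seq_len(nf)) {
    u <- cert[fi, ]
    if (max(u) == 0) codes[fi] <- "G"
    else codes[fi] <- teeth[which.max(u)]   # first max = lowest class index
  }
  codes
}

test_that("unprojection counts distinct views, ignores background", {
  jaw <- small_jaw()
  poses <- sample_views(list(jaw$landmarks["R2", 1:3], jaw$landmarks["R2", 4:6]), n = 4)
  views <- render_sequence(jaw$mesh, poses, 48L)
  records <- lapply(views, `[[`, "record")
  zero <- array(0L, dim = c(4, 48, 48))
  up0 <- unproject_masks(zero, records, n_faces(jaw$mesh))
  expect_length(up0$faces, 0)
  ones <- array(1L, dim = c(4, 48, 48))
  up1 <- unproject_masks(ones, records, n_faces(jaw$mesh))
  # all-ones masks unproject to exactly the visible-face union
  expect_setequal(up1$faces, sort(unique(unlist(lapply(records, `[[`, "visible_faces")))))
  expect_true(all(up1$hits[up1$faces] == up1$visible[up1$faces]))
  expect_true(all(up1$hits <= 4))
  expect_error(unproject_masks(ones, records[1:3], 10), "length mismatch")
})

test_that("certainty table ratios and fallbacks", {
  pt <- list(
    L1 = list(faces = 1:2, hits = c(3L, 4L, 0L), visible = c(4L, 4L, 0L)),
    L2 = list(faces = 1L, hits = c(2L, 0L, 0L), visible = c(4L, 0L, 2L))
  )
  tab <- build_certainty(pt, 3L)
  expect_equal(unname(tab$certainty[1, "L1"]), 0.75)
  expect_equal(unname(tab$certainty[2, "L1"]), 1.0)
  expect_equal(unname(tab$certainty[3, "L1"]), 0)      # never visible -> 0
  expect_equal(unname(tab$certainty[1, "L2"]), 0.5)
  expect_true(all(tab$certainty >= 0 & tab$certainty <= 1))
})

test_that("region voting takes the argmax with documented tie-breaks", {
  pt <- list(
    L1 = list(hits = c(8L, 6L, 0L), visible = c(10L, 10L, 0L)),
    L2 = list(hits = c(5L, 6L, 0L), visible = c(10L, 10L, 0L))
  )
  tab <- build_certainty(pt, 3L)
  lab <- region_voting(tab)
  expect_equal(as.character(lab), c("L1", "L1", "G"))  # 0.8>0.5; tie 0.6 -> L1; all 0 -> G
  # single assignment by construction
  expect_length(lab, 3)
})

test_that("full unproject-vote path matches the brute-force oracle", {
  set.seed(31)
  # tiny scene: two separated raised bumps on a small grid
  m <- plane_grid_mesh(7, 5)
  z <- m$vertices[, 3]
  b1 <- (m$vertices[, 1] - 1.5)^2 + (m$vertices[, 2] - 2.5)^2 < 2
  b2 <- (m$vertices[, 1] - 5.5)^2 + (m$vertices[, 2] - 2.5)^2 < 2
  z[b1 | b2] <- 1
  m$vertices[, 3] <- z
  expect_lte(n_faces(m), 200)
  teeth <- c("R1", "R2")
  ctrs <- list(R1 = c(1.5, 2.5, 1), R2 = c(5.5, 2.5, 1))
  ptv <- list()
  per_tooth <- list()
  for (tooth in teeth) {
    poses <- sample_views(list(ctrs[[tooth]] + c(-0.3, 0, 0), ctrs[[tooth]] + c(0.3, 0, 0)),
                          n = 5, radius = 9, half_extent = 5)
    views <- render_sequence(m, poses, 24L)
    masks <- array(rbinom(5 * 24 * 24, 1, 0.4), dim = c(5, 24, 24))
    ptv[[tooth]] <- list(views = views, masks = masks)
    per_tooth[[tooth]] <- unproject_masks(masks, lapply(views, `[[`, "record"), n_faces(m))
  }
  tab <- build_certainty(per_tooth, n_faces(m))
  lab <- region_voting(tab)
  expect_equal(as.character(lab), vote_oracle(m, ptv, 5))
})

test_that("connected-component cleanup keeps the largest region", {
  # plane grid with a main region and a detached satellite of the same class
  pg <- plane_grid_mesh(9, 4)
  cen <- (pg$vertices[pg$faces[, 1], ] + pg$vertices[pg$faces[, 2], ] +
          pg$vertices[pg$faces[, 3], ]) / 3
  main <- cen[, 1] < 3            # big block
  sat <- cen[, 1] > 7             # small block, disconnected from main
  lab <- face_labels(ifelse(main | sat, "L1", "G"))
  expect_gt(sum(main), sum(sat))
  hits <- matrix(0L, n_faces(pg), 16, dimnames = list(NULL, tooth_class_codes(FALSE)))
  vis <- hits
  hits[main | sat, "L1"] <- 3L
  vis[main | sat, "L1"] <- 4L
  tab <- structure(list(hits = hits, visible = vis,
                        certainty = ifelse(vis > 0, hits / pmax(vis, 1), 0)),
                   class = "certainty_table")
  out <- cca_cleanup(pg, lab, tab)
  expect_equal(sum(as.character(out) == "L1"), sum(main))
  # satellite faces had no other-class certainty -> gingiva
  expect_true(all(as.character(out)[sat] == "G"))
  # idempotent on an already-clean labeling
  out2 <- cca_cleanup(pg, out, tab)
  expect_equal(as.character(out2), as.character(out))
})

test_that("discarded faces move to the next-certain adjacent class", {
  # one strip: left block L1, right block L2; a lone L1 face inside L2's block
  pg <- plane_grid_mesh(9, 1)
  cen <- (pg$vertices[pg$faces[, 1], ] + pg$vertices[pg$faces[, 2], ] +
          pg$vertices[pg$faces[, 3], ]) / 3
  lab <- ifelse(cen[, 1] < 5, "L1", "L2")
  lone <- which(lab == "L2")[4]
  lab[lone] <- "L1"               # creates a detached L1 satellite
  labf <- face_labels(lab)
  hits <- matrix(0L, n_faces(pg), 16, dimnames = list(NULL, tooth_class_codes(FALSE)))
  vis <- hits
  hits[lab == "L1", "L1"] <- 2L; vis[lab == "L1", "L1"] <- 2L
  hits[, "L2"][lab == "L2" | seq_len(n_faces(pg)) == lone] <- 1L
  vis[, "L2"][lab == "L2" | seq_len(n_faces(pg)) == lone] <- 2L
  tab <- structure(list(hits = hits, visible = vis,
                        certainty = ifelse(vis > 0, hits / pmax(vis, 1), 0)),
                   class = "certainty_table")
  out <- cca_cleanup(pg, labf, tab)
  expect_equal(as.character(out)[lone], "L2")
  # every tooth class now forms exactly one component
  expect_true(all(dentseg:::tooth_component_count(pg, out) == 1))
})

test_that("voting beats last-writer-wins on double-claimed faces", {
  # two teeth whose dilated masks overlap across the gap between them
  jaw <- small_jaw()
  teeth <- c("R1", "R2")
  per_tooth <- list()
  for (tooth in teeth) {
    poses <- sample_views(list(jaw$landmarks[tooth, 1:3], jaw$landmarks[tooth, 4:6]), n = 7)
    views <- render_sequence(jaw$mesh, poses, 96L)
    masks <- make_targets(jaw$labels, tooth, views)
    for (v in seq_len(dim(masks)[1])) {
      masks[v, , ] <- dilate_mask(masks[v, , ], 3L)
    }
    per_tooth[[tooth]] <- unproject_masks(masks, lapply(views, `[[`, "record"),
                                          n_faces(jaw$mesh))
  }
  tab <- build_certainty(per_tooth, n_faces(jaw$mesh))
  voted <- region_voting(tab)
  # last-writer-wins: assign sequentially in canonical order, overwriting
  lww <- rep("G", n_faces(jaw$mesh))
  for (tooth in teeth) lww[per_tooth[[tooth]]$faces] <- tooth
  lww <- face_labels(lww)
  # restrict scoring to faces claimed by at least one tooth
  claimed <- sort(unique(c(per_tooth[[1]]$faces, per_tooth[[2]]$faces)))
  double_claimed <- intersect(per_tooth[[1]]$faces, per_tooth[[2]]$faces)
  expect_gt(length(double_claimed), 0)
  w_vote <- mean(vapply(teeth, function(tt) weighted_iou(jaw$mesh, jaw$labels, voted, tt),
                        numeric(1)))
  w_lww <- mean(vapply(teeth, function(tt) weighted_iou(jaw$mesh, jaw$labels, lww, tt),
                       numeric(1)))
  expect_gt(w_vote, w_lww)
})
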