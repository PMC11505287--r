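# Brute-force oracles, written independently of the implementation paths
# (plain double loops over faces / point pairs).

wiou_oracle <- function(mesh, gt, pred, cls) {
  inter <- 0; uni <- 0
  for (fi in seq_len(n_faces(mesh))) {
    tri <- mesh$vertices[mesh$faces[fi, ], ]
    a <- sqrt(sum((tri[1, ] - tri[2, ])^2))
    b <- sqrt(sum((tri[2, ] - tri[3, ])^2))
    cc <- sqrt(sum((tri[3, ] - tri[1, ])^2))
    s <- (a + b + cc) / 2
    area <- sqrt(max(0, s * (s - a) * (s - b) * (s - cc)))
    g <- as.character(gt)[fi] == cls
    p <- as.character(pred)[fi] == cls
    if (g && p) inter <- inter + area
    if (g || p) uni <- uni + area
  }
  if (uni == 0) return(if (any(as.character(gt) == cls) == any(as.character(pred) == cls)) 1 else 0)
  inter / uni
}

hausdorff_oracle <- function(A, B) max(max(nnd_oracle(A, B)), max(nnd_oracle(B, A)))

hausdorff95_oracle <- function(A, B) {
  max(quantile(nnd_oracle(A, B), 0.95, type = 7),
      quantile(nnd_oracle(B, A), 0.95, type = 7))
}

dice_oracle <- function(p, r, eps) {
  sp <- 0; sr <- 0; spr <- 0
  for (i in seq_along(p)) {
    sp <- sp + p[i]; sr <- sr + r[i]; spr <- spr + p[i] * r[i]
  }
  1 - (2 * spr + eps) / (sp + sr + eps)
}

# helpers local to this file
rotation_about_axis_test <- function(axis, angle) {
  dentseg:::rotation_about_axis(axis, angle)
}

perturbed_prediction <- function(jaw) {
  # flip a sprinkling of faces to the neighboring class to emulate errors
  lab <- as.character(jaw$labels)
  set.seed(3)
  flip <- sample(which(lab != "G"), 40)
  lab[flip] <- "G"
  face_labels(lab)
}

test_that("weighted IoU closed forms", {
  jaw <- small_jaw()
  expect_equal(weighted_iou(jaw$mesh, jaw$labels, jaw$labels, "R1"), 1.0)
  swapped <- face_labels(ifelse(as.character(jaw$labels) == "R1", "G",
                                ifelse(as.character(jaw$labels) == "G", "R1",
                                       as.character(jaw$labels))))
  expect_equal(weighted_iou(jaw$mesh, jaw$labels, swapped, "R1"), 0.0)
  # two faces of areas 1 and 3: prediction keeps only the larger
  m <- tri_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(3, 0, 0), c(0, 2, 0)),
                rbind(c(1, 2, 3), c(1, 4, 5)))
  expect_equal(face_areas(m), c(1, 3))
  gt <- face_labels(c("L1", "L1"))
  pred <- face_labels(c("G", "L1"))
  expect_equal(weighted_iou(m, gt, pred, "L1"), 3 / 4)
})

test_that("Hausdorff distances: closed forms and percentile behavior", {
  A <- rbind(c(0, 0, 0))
  B <- rbind(c(3, 4, 0))
  expect_equal(hausdorff(A, A), 0)
  expect_equal(hausdorff(A, B), 5)
  expect_equal(hausdorff(rbind(c(0, 0, 0), c(1, 0, 0)), A), 1)
  expect_error(hausdorff(A, matrix(numeric(0), ncol = 3)), "undefined")
  # 96 coincident points + 4 displaced by 1: dH95 < 1 while dH = 1
  P <- as.matrix(expand.grid(x = seq(0, 12, by = 3), y = seq(0, 12, by = 3),
                             z = c(0, 3, 6, 9)))
  P <- P[1:100, ]
  Q <- P
  Q[1:4, 1] <- Q[1:4, 1] + 1
  expect_equal(hausdorff(P, Q), 1)
  expect_lt(hausdorff_95(P, Q), 1)
  expect_lte(hausdorff_95(P, Q), hausdorff(P, Q))
})

test_that("metrics are invariant under joint rigid transforms", {
  jaw <- small_jaw()
  xf <- rigid_transform(rotation_about_axis_test(c(1, 2, 3), 0.7), c(4, -2, 9))
  m2 <- apply_transform(jaw$mesh, xf)
  pred <- perturbed_prediction(jaw)
  for (cls in c("L3", "R5")) {
    expect_equal(weighted_iou(m2, jaw$labels, pred, cls),
                 weighted_iou(jaw$mesh, jaw$labels, pred, cls), tolerance = 1e-9)
    b1 <- label_boundary_vertices(jaw$mesh, jaw$labels, cls)
    b2 <- label_boundary_vertices(jaw$mesh, pred, cls)
    expect_equal(hausdorff(transform_points(b1, xf), transform_points(b2, xf)),
                 hausdorff(b1, b2), tolerance = 1e-9)
    expect_equal(hausdorff(b1, b2), hausdorff(b2, b1))
  }
})

test_that("weighted IoU is invariant to label-preserving refinement", {
  # subdividing a face into same-labeled children keeps the value
  m <- quad_mesh()
  gt <- face_labels(c("L1", "G"))
  pred <- face_labels(c("L1", "L1"))
  v0 <- weighted_iou(m, gt, pred, "L1")
  # split face 1 at its centroid into three children
  cen <- colMeans(m$vertices[m$faces[1, ], ])
  m2 <- tri_mesh(rbind(m$vertices, cen),
                 rbind(c(1, 2, 5), c(2, 3, 5), c(1, 5, 3), m$faces[2, , drop = FALSE]))
  gt2 <- face_labels(c("L1", "L1", "L1", "G"))
  pred2 <- face_labels(c("L1", "L1", "L1", "L1"))
  expect_equal(weighted_iou(m2, gt2, pred2, "L1"), v0, tolerance = 1e-12)
})

test_that("metric implementations match brute-force oracles on random fixtures", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(5:9, 1)
    A <- matrix(rnorm(3 * n), ncol = 3)
    B <- matrix(rnorm(3 * sample(4:8, 1)), ncol = 3)
    expect_equal(hausdorff(A, B), hausdorff_oracle(A, B), tolerance = 1e-12)
    expect_equal(hausdorff_95(A, B), hausdorff95_oracle(A, B),
                 ignore_attr = TRUE, tolerance = 1e-12)
    p <- runif(24); r <- rbinom(24, 1, 0.5); eps <- runif(1, 0.1, 2)
    expect_equal(dice_loss(p, r, eps), dice_oracle(p, r, eps), tolerance = 1e-12)
  }
  jaw <- small_jaw()
  pred <- perturbed_prediction(jaw)
  for (cls in c("L1", "L5", "R8")) {
    expect_equal(weighted_iou(jaw$mesh, jaw$labels, pred, cls),
                 wiou_oracle(jaw$mesh, jaw$labels, pred, cls), tolerance = 1e-9)
  }
})

test_that("evaluate_case aggregates per tooth and flags missing predictions", {
  jaw <- small_jaw()
  ev <- evaluate_case(jaw$mesh, jaw$labels, jaw$labels)
  expect_true(all(ev$per_tooth$wiou == 1))
  expect_true(all(ev$per_tooth$dh95 == 0))
  expect_equal(ev$case$mean_wiou, 1)
  # drop one tooth entirely from the prediction
  pred <- face_labels(ifelse(as.character(jaw$labels) == "L4", "G",
                             as.character(jaw$labels)))
  ev2 <- evaluate_case(jaw$mesh, jaw$labels, pred)
  row <- ev2$per_tooth[ev2$per_tooth$tooth == "L4", ]
  expect_equal(row$wiou, 0)
  expect_true(row$missing_in_pred)
  expect_true(is.na(row$dh95))
  # relabeling one boundary face strictly lowers that tooth's W-IoU
  lab <- as.character(jaw$labels)
  fi <- which(lab == "R2")[1]
  lab[fi] <- "G"
  ev3 <- evaluate_case(jaw$mesh, jaw$labels, face_labels(lab))
  expect_lt(ev3$per_tooth$wiou[ev3$per_tooth$tooth == "R2"], 1)
})

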