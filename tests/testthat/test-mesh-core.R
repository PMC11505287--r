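test_that("face areas match closed forms and scale quadratically", {
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(face_areas(m), 0.5)
  expect_equal(sum(face_areas(cube_mesh())), 6.0)
  jaw <- small_jaw()
  a1 <- face_areas(jaw$mesh)
  m2 <- jaw$mesh
  m2$vertices <- m2$vertices * 2
  expect_equal(face_areas(m2), 4 * a1, tolerance = 1e-12)
})

test_that("face areas agree with a Heron's-formula oracle", {
  jaw <- small_jaw()
  m <- jaw$mesh
  idx <- seq(1, n_faces(m), by = 17)
  heron <- vapply(idx, function(fi) {
    tri <- m$vertices[m$faces[fi, ], ]
    a <- sqrt(sum((tri[1, ] - tri[2, ])^2))
    b <- sqrt(sum((tri[2, ] - tri[3, ])^2))
    cc <- sqrt(sum((tri[3, ] - tri[1, ])^2))
    s <- (a + b + cc) / 2
    sqrt(max(0, s * (s - a) * (s - b) * (s - cc)))
  }, numeric(1))
  expect_equal(face_areas(m)[idx], heron, tolerance = 1e-9)
})

test_that("degenerate faces are dropped at load with a warning log", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))   # second face collinear, zero area
  soup <- tri_mesh(v, f, validate = FALSE)
  path <- tempfile(fileext = ".obj")
  dentseg:::write_obj(soup, path)
  expect_message(m <- read_mesh(path), "dropped 1 degenerate")
  expect_equal(n_faces(m), 1L)
})

test_that("mesh IO round trips through OBJ, PLY and both STL dialects", {
  jaw <- small_jaw()
  m <- jaw$mesh
  for (fmt in c("obj", "ply")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$faces, m$faces)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  }
  # STL stores per-triangle float32 vertices; compare the triangle soups
  for (fmt in c("stl", "stl_ascii")) {
    path <- tempfile(fileext = ".stl")
    write_mesh(m, path, format = fmt)
    m2 <- read_mesh(path)
    expect_equal(n_faces(m2), n_faces(m))
    soup <- function(mm) cbind(mm$vertices[mm$faces[, 1], ],
                               mm$vertices[mm$faces[, 2], ],
                               mm$vertices[mm$faces[, 3], ])
    tol <- if (fmt == "stl") 1e-5 else 1e-7
    expect_equal(soup(m2), soup(m), tolerance = tol)
  }
})

test_that("empty and unreadable mesh files raise errors", {
  empty <- tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_mesh(empty), "empty")
  expect_error(read_mesh(tempfile(fileext = ".stl")), "not found")
})

test_that("label sidecars write one code per line and read back exactly", {
  path <- tempfile(fileext = ".labels.txt")
  write_labels(face_labels(c("G", "G", "L1")), path)
  expect_identical(readLines(path), c("G", "G", "L1"))
  for (seed in 1:5) {
    lab <- random_labels(40, seed)
    write_labels(lab, path)
    expect_equal(as.character(read_labels(path)), as.character(lab))
  }
})

test_that("label sidecar length and code validation", {
  m <- quad_mesh()
  path <- tempfile()
  writeLines(c("G", "G", "L1"), path)
  expect_error(read_labels(path, mesh = m), "3 entries.*2 faces")
  writeLines(c("G", "X9"), path)
  expect_error(read_labels(path, mesh = m), "unknown tooth class")
  expect_error(write_labels(face_labels(c("G", "G", "G")), path, mesh = m),
               "3 entries.*2 faces")
})

test_that("JSON label sidecar variant is accepted on read", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_faces = 2, labels = c("L3", "G")), path,
                       auto_unbox = TRUE)
  lab <- read_labels(path, mesh = quad_mesh())
  expect_equal(as.character(lab), c("L3", "G"))
})

test_that("face adjacency is symmetric with at most 3 neighbors on manifolds", {
  jaw <- small_jaw()
  adj <- face_adjacency(jaw$mesh)
  expect_true(all(lengths(adj$neighbors) <= 3))
  for (fi in seq(1, n_faces(jaw$mesh), by = 97)) {
    for (nb in adj$neighbors[[fi]]) {
      expect_true(fi %in% adj$neighbors[[nb]])
    }
  }
})

test_that("label boundary vertices sit on transitions and form closed loops", {
  m <- quad_mesh()
  lab_all_g <- face_labels(c("G", "G"))
  expect_equal(nrow(label_boundary_vertices(m, lab_all_g, "G")), 0L)
  lab <- face_labels(c("L1", "G"))
  bv <- label_boundary_vertices(m, lab, "L1")
  # the two vertices shared by the diagonal edge
  expect_equal(bv[order(bv[, 1]), ], rbind(c(0, 0, 0), c(1, 1, 0)),
               ignore_attr = TRUE)
  # patch on a plane grid: boundary forms one closed loop
  pg <- plane_grid_mesh(6, 6)
  cen <- (pg$vertices[pg$faces[, 1], ] + pg$vertices[pg$faces[, 2], ] +
          pg$vertices[pg$faces[, 3], ]) / 3
  inside <- cen[, 1] > 1.4 & cen[, 1] < 4.6 & cen[, 2] > 1.4 & cen[, 2] < 4.6
  lab <- face_labels(ifelse(inside, "R1", "G"))
  bv <- label_boundary_vertices(pg, lab, "R1")
  expect_gt(nrow(bv), 4)
  # each boundary vertex has exactly two boundary-vertex neighbors at
  # distance 1 or sqrt(2) along the loop on this grid: check connectivity
  d <- as.matrix(dist(bv))
  diag(d) <- Inf
  expect_true(all(apply(d, 1, min) <= sqrt(2) + 1e-12))
})

test_that("boundary transition symmetry between a class and its complement", {
  jaw <- small_jaw()
  lab <- jaw$labels
  for (cls in c("L1", "R6")) {
    bv <- label_boundary_vertices(jaw$mesh, lab, cls)
    flipped <- face_labels(ifelse(as.character(lab) == cls, "G", cls))
    bv2 <- label_boundary_vertices(jaw$mesh, flipped, cls)
    expect_true(nrow(bv) > 0)
    # the transition edge set is unchanged by complementation
    expect_setequal(apply(round(bv, 9), 1, paste, collapse = ","),
                    apply(round(bv2, 9), 1, paste, collapse = ","))
  }
})

test_that("tooth class codes, indices and the type signal are a bijection", {
  codes <- tooth_class_codes()
  expect_length(codes, 17)
  expect_equal(tooth_class_index("L1"), 0L)
  expect_equal(tooth_class_index("R8"), 15L)
  expect_equal(tooth_class_index("G"), 16L)
  expect_setequal(tooth_arch_order(), tooth_class_codes(include_gingiva = FALSE))
  sig <- vapply(tooth_class_codes(include_gingiva = FALSE), tooth_type_signal,
                numeric(1))
  expect_length(unique(sig), 16)
  expect_true(all(sig > 0 & sig <= 1))
  expect_equal(unname(sig["L8"]), 1 / 16)
  expect_error(tooth_type_signal("G"), "no tooth-type")
})
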