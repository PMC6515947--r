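# PDB reading, face-plane fitting, residue face classification and zone
# composition.

test_that("PDB reading extracts CA coordinates, tolerates gaps, keeps first altloc", {
  lines <- c(pdb_line(1, 1, 1, 0, 0),
             pdb_line(2, 2, 2, 0, 0),
             pdb_line(3, 3, 3, 0, 1))
  m <- read_structure(write_pdb_fixture(lines))
  expect_equal(m$resno, 1:3)
  expect_equal(m$x, c(1, 2, 3))
  expect_equal(m$z, c(0, 0, 1))

  # missing residue 2: resolved set excludes it, unresolved records it
  gap <- read_structure(write_pdb_fixture(lines[c(1, 3)]))
  expect_equal(gap$resno, c(1L, 3L))
  expect_equal(attr(gap, "unresolved"), 2L)

  # duplicated altloc CA records: the first is retained
  alt <- c(pdb_line(1, 1, 1, 0, 0),
           pdb_line(2, 2, 5, 0, 0, altloc = "A"),
           pdb_line(3, 2, 9, 9, 9, altloc = "B"),
           pdb_line(4, 3, 3, 0, 0))
  ma <- read_structure(write_pdb_fixture(alt))
  expect_equal(ma$x[ma$resno == 2], 5)

  expect_error(read_structure(write_pdb_fixture(lines), chain = "Z"),
               class = "pepzone_error_no_such_chain")
  ins <- pdb_line(1, 1, 1, 0, 0, icode = "A")
  expect_error(read_structure(write_pdb_fixture(c(lines, ins))),
               class = "pepzone_error_bad_structure")
})

test_that("plane fit recovers an exact plane and rejects degenerate geometry", {
  set.seed(20)
  base <- data.frame(resno = 1:40,
                     x = runif(40, 0, 50), y = runif(40, 0, 50), z = 0)
  base$z[5:9] <- 5  # anchors above the plane
  class(base) <- c("structure_model", class(base))
  pl <- fit_face_plane(base, anchors = 5:9)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 0.05)
  expect_gt(pl$normal[3], 0)  # oriented toward the anchors

  # rigid rotation rotates the plane with the cloud; signed distances persist
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  rot <- apply_rigid(base, R, shift = c(10, -4, 7))
  pl_rot <- fit_face_plane(rot, anchors = 5:9)
  d0 <- as.matrix(base[, c("x", "y", "z")]) %*% pl$normal - pl$offset
  d1 <- as.matrix(rot[, c("x", "y", "z")]) %*% pl_rot$normal - pl_rot$offset
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-8)

  line <- data.frame(resno = 1:10, x = 1:10, y = 2 * (1:10), z = 3 * (1:10))
  expect_error(fit_face_plane(line, anchors = 1:2),
               class = "pepzone_error_degenerate_geometry")
  flat <- base; flat$z <- 0
  expect_error(fit_face_plane(flat, anchors = 5:9),
               class = "pepzone_error_anchors_on_plane")
  expect_error(fit_face_plane(base, anchors = 200:204),
               class = "pepzone_error_degenerate_geometry")
})

test_that("signed-distance classification labels L, J and the edge band", {
  m <- data.frame(resno = 1:6,
                  x = c(0, 10, 20, 30, 40, 50),
                  y = c(0, 10, 20, 5, 15, 25),
                  z = c(5, -5, 1.0, 5, -5, 0.2))
  class(m) <- c("structure_model", class(m))
  # use a fixed plane: z = 0, L above
  plane <- structure(list(normal = c(0, 0, 1), centroid = c(0, 0, 0), offset = 0,
                          anchors = 1L, edge_delta = 1.5), class = "face_plane")
  lab <- classify_faces(m, plane)
  expect_identical(unname(lab), c("L", "J", "edge", "L", "J", "edge"))
})

test_that("generated structures classify to generator truth on all shapes", {
  for (shape in c("fishhook", "plane", "helix")) {
    g <- gen_structure(shape = shape, l_spans = L_SPANS, j_spans = J_SPANS,
                       seed = 21)
    pl <- fit_face_plane(g$model, anchors = 39:43)
    lab <- classify_faces(g$model, pl)
    non_edge <- g$truth$labels != "edge"
    expect_identical(lab[non_edge], g$truth$labels[non_edge])
  }
})

test_that("face labels are invariant under rigid motion and flip with the anchors", {
  g <- gen_structure(shape = "fishhook", l_spans = L_SPANS, j_spans = J_SPANS,
                     seed = 22)
  pl <- fit_face_plane(g$model, anchors = 39:43)
  lab <- classify_faces(g$model, pl)

  R <- rotation_matrix(c(-1, 0.5, 2), 0.8)
  moved <- apply_rigid(g$model, R, shift = c(-30, 12, 100))
  lab_moved <- classify_faces(moved, fit_face_plane(moved, anchors = 39:43))
  expect_identical(lab_moved, lab)

  # anchoring on a J-side span flips every L/J label, edge unchanged
  pl_flip <- fit_face_plane(g$model, anchors = 85:107)
  lab_flip <- classify_faces(g$model, pl_flip)
  expect_identical(unname(lab_flip[lab == "L"]),
                   rep("J", sum(lab == "L")))
  expect_identical(unname(lab_flip[lab == "J"]),
                   rep("L", sum(lab == "J")))
  expect_identical(lab_flip[lab == "edge"], lab[lab == "edge"])
})

test_that("zone face composition reports planted sidedness and handles gaps", {
  g <- gen_structure(shape = "fishhook", l_spans = L_SPANS, j_spans = J_SPANS,
                     seed = 23)
  pl <- fit_face_plane(g$model, anchors = 39:43)
  lab <- classify_faces(g$model, pl)
  zones <- data.frame(zone = 1:4,
                      span_start = c(129, 181, 245, 85),
                      span_end = c(151, 219, 279, 107))
  comp <- zone_face_fraction(zones, lab)
  expect_equal(comp$majority, c("L", "L", "L", "J"))
  expect_true(all(comp$frac_L[1:3] > 0.9))
  expect_true(all(comp$n_unresolved == 0))
  expect_equal(rowSums(comp[, c("frac_L", "frac_J", "frac_edge")]), rep(1, 4),
               ignore_attr = TRUE)

  # a zone over only-unresolved residues errors
  sub <- g$model[g$model$resno <= 100, ]
  lab_sub <- lab[as.integer(names(lab)) <= 100]
  expect_error(zone_face_fraction(data.frame(zone = 1, span_start = 200,
                                             span_end = 210), lab_sub),
               class = "pepzone_error_empty_zone")
})

test_that("face overlay export writes readable B-factors encoding the faces", {
  g <- gen_structure(n_res = 30, shape = "plane",
                     l_spans = list(c(3, 7)), j_spans = list(c(12, 16)), seed = 24)
  pl <- fit_face_plane(g$model, anchors = 3:7)
  lab <- classify_faces(g$model, pl)
  out <- tempfile(fileext = ".pdb")
  write_face_overlay(g$model, lab, out)
  back <- bio3d::read.pdb(out, verbose = FALSE)
  ca <- back$atom[back$atom$elety == "CA", ]
  expect_equal(nrow(ca), 30)
  expect_equal(unname(c(L = 1, J = -1, edge = 0)[lab]), ca$b)
})
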