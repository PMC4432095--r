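test_that("object construction validates point counts and degeneracy", {
  p2 <- rbind(c(0, 0, 0), c(0, 0, 1))
  p3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(geom_object("arrow", p2), "geom_object")
  expect_s3_class(geom_object("triangle", p3), "geom_object")
  expect_error(geom_object("triangle", p2), "3 point")
  expect_error(geom_object("triangle", rbind(c(0, 0, 0), c(1, 0, 0),
                                             c(2, 0, 0))), "collinear")
  expect_error(geom_object("sphere", matrix(0, 1, 3)), "radius")
  expect_error(geom_object("arrow", p2, opacity = 1.5), "0, 1")
})

test_that("two triangles sharing an edge compose a square", {
  doc <- mfx_doc(make_molecule("h2"))
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  doc <- add_object(doc, "triangle", points = sq[c(1, 2, 3), ])
  doc <- add_object(doc, "triangle", points = sq[c(1, 3, 4), ])
  expect_length(doc$objects, 2L)
  verts <- unique(rbind(object_mesh(doc$objects[[1]])$vertices,
                        object_mesh(doc$objects[[2]])$vertices))
  expect_equal(nrow(verts), 4L)   # the shared edge joins them
})

test_that("tetrahedra drawn around SiO4 silicon use the oxygen corners", {
  s <- make_molecule("sio4")
  doc <- mfx_doc(s)
  faces <- combn(2:5, 3)
  for (k in seq_len(ncol(faces)))
    doc <- add_object(doc, "triangle", selection = faces[, k],
                      opacity = 0.3)
  expect_length(doc$objects, 4L)
  for (ob in doc$objects) expect_equal(ob$opacity, 0.3)
})

test_that("objects survive the document round-trip exactly", {
  td <- withr::local_tempdir()
  doc <- mfx_doc(make_molecule("water"))
  doc <- add_object(doc, "parallelepiped",
                    points = rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
                                   c(0.3, 0.1, 2)),
                    rgba = c(0.2, 0.4, 0.6, 1), opacity = 1.0)
  p <- file.path(td, "obj.mfx")
  write_mfx(doc, p)
  d2 <- read_mfx(p)
  ob <- d2$objects[[1]]
  expect_equal(ob$kind, "parallelepiped")
  expect_lt(max(abs(ob$points - doc$objects[[1]]$points)), 1e-6)
  expect_identical(ob$opacity, 1.0)
  expect_equal(ob$rgba, c(0.2, 0.4, 0.6, 1))
})

test_that("dipole arrows point along the dipole and skip zero dipoles", {
  w <- make_molecule("water")
  w$metadata$dipole <- c(0, 0, 2.5)
  doc <- dipole_arrow(mfx_doc(w))
  expect_length(doc$objects, 1L)
  d <- doc$objects[[1]]$points[2, ] - doc$objects[[1]]$points[1, ]
  expect_equal(d / sqrt(sum(d^2)), c(0, 0, 1), tolerance = 1e-12)

  w0 <- make_molecule("water")
  w0$metadata$dipole <- c(0, 0, 0)
  expect_length(dipole_arrow(mfx_doc(w0))$objects, 0L)

  # droplet: one arrow per molecule, parallel to its dipole
  dr <- make_droplet(25, radius = 14, seed = 7)
  docd <- dipole_arrow(mfx_doc(dr))
  mu <- matrix(dr$metadata$molecule_dipoles, ncol = 3)
  expect_length(docd$objects, 25L)
  for (k in seq_len(25)) {
    v <- docd$objects[[k]]$points[2, ] - docd$objects[[k]]$points[1, ]
    cosang <- sum(v * mu[k, ]) / sqrt(sum(v^2) * sum(mu[k, ]^2))
    expect_equal(cosang, 1, tolerance = 1e-9)
  }
})

test_that("PLY export writes matching counts and parses back", {
  td <- withr::local_tempdir()
  s <- object_mesh(geom_object("sphere", matrix(0, 1, 3), magnitude = 1.5),
                   segments = 10)
  p <- file.path(td, "s.ply")
  export_scene(s, p)

  # header counts match the mesh (checked on the raw text, independently)
  lines <- readLines(p)
  expect_equal(as.integer(sub("element vertex ", "",
                              grep("^element vertex", lines, value = TRUE))),
               nrow(s$vertices))
  expect_equal(as.integer(sub("element face ", "",
                              grep("^element face", lines, value = TRUE))),
               nrow(s$triangles))

  m2 <- read_ply(p)
  expect_equal(nrow(m2$vertices), nrow(s$vertices))
  expect_equal(nrow(m2$triangles), nrow(s$triangles))
  expect_lt(max(abs(m2$vertices - s$vertices)), 1e-6)

  # constant scalar yields a single colour
  s$vertex_scalar <- rep(1, nrow(s$vertices))
  export_scene(s, p)
  rgb <- attr(read_ply(p), "rgb")
  expect_equal(nrow(unique(round(rgb, 6))), 1L)

  # diverging map: white at zero, full endpoints at +/- max|scalar|
  cols <- diverging_colors(c(-2, 0, 2))
  expect_equal(cols[2, ], c(1, 1, 1), tolerance = 1e-9)
  expect_true(cols[1, 3] > cols[1, 1])   # negative end is blue
  expect_true(cols[3, 1] > cols[3, 3])   # positive end is red
  # scaling the scalars leaves the normalized colours unchanged
  expect_equal(diverging_colors(c(-4, 0, 4)), cols, tolerance = 1e-9)
})
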