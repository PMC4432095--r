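test_that("XYZ files round-trip elements, coordinates and charges", {
  td <- withr::local_tempdir()
  b <- make_molecule("benzene")
  p <- file.path(td, "b.xyz")
  write_xyz(b, p)
  b2 <- read_xyz(p)
  expect_identical(b2$element, b$element)
  expect_lt(max(abs(b2$xyz - b$xyz)), 1e-6)

  # charges survive as a fifth column
  w <- make_molecule("water")
  w$charge <- c(-0.8, 0.4, 0.4)
  pq <- file.path(td, "wq.xyz")
  write_xyz(w, pq)
  expect_equal(read_xyz(pq)$charge, w$charge, tolerance = 1e-9)
})

test_that("concatenated XYZ blocks become frames; n = 0 parses empty", {
  td <- withr::local_tempdir()
  b <- make_molecule("benzene")
  tr <- normal_mode_frames(b, matrix(0.05, n_atoms(b), 3), 0.4, 3)
  p <- file.path(td, "traj.xyz")
  write_xyz(tr, p)
  tr2 <- read_xyz(p)
  expect_equal(length(tr2$frames), 3L)
  for (k in 1:3) expect_lt(max(abs(tr2$frames[[k]] - tr$frames[[k]])), 1e-6)

  pe <- file.path(td, "empty.xyz")
  writeLines(c("0", "nothing"), pe)
  expect_equal(n_atoms(read_xyz(pe)), 0L)
})

test_that("malformed XYZ errors carry the offending line number", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.xyz")
  writeLines(c("2", "t", "H 0 0 0", "H 0 zero 0"), p)
  expect_error(read_xyz(p), "line 4")
  writeLines(c("3", "t", "H 0 0 0"), p)
  expect_error(read_xyz(p), "count")
})

test_that("any XYZ file parses as a document with empty sections", {
  td <- withr::local_tempdir()
  p <- file.path(td, "w.xyz")
  write_xyz(make_molecule("water"), p)
  doc <- read_mfx(p)
  expect_s3_class(doc, "mfx_doc")
  expect_equal(n_atoms(doc$molecule), 3L)
  expect_length(doc$grids, 0L)
  expect_length(doc$objects, 0L)
})

test_that("documents round-trip payloads and are byte-stable", {
  td <- withr::local_tempdir()
  w <- make_molecule("water")
  w$metadata$dipole <- c(0, 0, 2.5)
  g <- scalar_grid(c(0, 0, 0), diag(3) * 0.4,
                   array(sin(1:27), c(3, 3, 3)), label = "toy")
  doc <- mfx_doc(w, grids = list(g))
  doc <- add_object(doc, "arrow", points = rbind(c(0, 0, 0), c(0, 0, 2)),
                    opacity = 1.0)
  p1 <- file.path(td, "w.mfx"); p2 <- file.path(td, "w2.mfx")
  write_mfx(doc, p1)
  d2 <- read_mfx(p1)
  expect_length(d2$grids, 1L)
  expect_length(d2$objects, 1L)
  expect_equal(d2$molecule$metadata$dipole, c(0, 0, 2.5))
  expect_lt(max(abs(d2$grids[[1]]$values - g$values)), 1e-9)
  expect_equal(d2$objects[[1]]$opacity, 1.0)

  # write(read(write(...))) is byte-identical
  write_mfx(d2, p2)
  expect_identical(readLines(p2), readLines(p1))

  # the header lines are themselves a valid XYZ file
  hdr <- file.path(td, "head.xyz")
  writeLines(head(readLines(p1), 2 + n_atoms(w)), hdr)
  hx <- read_xyz(hdr)
  expect_lt(max(abs(hx$xyz - w$xyz)), 1e-6)
})

test_that("unknown XML sections are preserved verbatim", {
  td <- withr::local_tempdir()
  p <- file.path(td, "x.mfx")
  write_mfx(mfx_doc(make_molecule("h2")), p)
  writeLines(c(readLines(p), "<mfx version=\"1.0\">",
               "  <custom flavor=\"strange\">7 8 9</custom>", "</mfx>"), p)
  doc <- read_mfx(p)
  expect_length(doc$extra, 1L)
  expect_match(doc$extra, "strange")
  p2 <- file.path(td, "x2.mfx")
  write_mfx(doc, p2)
  expect_match(paste(readLines(p2), collapse = "\n"), "strange")
})

test_that("broken documents fail with section-level errors", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.mfx")
  write_mfx(mfx_doc(make_molecule("h2")), p)
  writeLines(c(readLines(p), "<mfx><grid></mfx>"), p)
  expect_error(read_mfx(p), "XML")
  writeLines("<mfx version=\"1.0\"></mfx>", p)
  expect_error(read_mfx(p), "header")
})

test_that("cube files round-trip lattice, values and atoms through bohr", {
  td <- withr::local_tempdir()
  xs <- seq(-2, 2, length.out = 8)
  pts <- as.matrix(expand.grid(xs, xs, xs))
  vals <- exp(-rowSums(pts^2))
  g <- scalar_grid(c(-2, -2, -2), diag(rep(xs[2] - xs[1], 3)),
                   array(vals, c(8, 8, 8)), label = "gaussian")
  g$molecule <- make_molecule("water")
  p <- file.path(td, "g.cube")
  write_grid_cube(g, p)
  g2 <- read_grid_cube(p)
  expect_lt(max(abs(g2$values - g$values)), 1e-10)
  expect_lt(max(abs(g2$axes - g$axes)), 1e-6)
  expect_lt(max(abs(g2$origin - g$origin)), 1e-6)
  expect_identical(g2$molecule$element, g$molecule$element)
  expect_lt(max(abs(g2$molecule$xyz - g$molecule$xyz)), 1e-6)

  # a 1-bohr step written externally reads back as 0.529177210903 A
  lines <- readLines(p)
  lines[4] <- "    8     1.000000     0.000000     0.000000"
  writeLines(lines, p)
  expect_equal(read_grid_cube(p)$axes[1, 1], 0.529177210903,
               tolerance = 1e-12)

  # origin zero maps to zero
  g0 <- scalar_grid(c(0, 0, 0), diag(3) * 0.5, array(0:7, c(2, 2, 2)))
  p0 <- file.path(td, "g0.cube")
  write_grid_cube(g0, p0)
  expect_equal(read_grid_cube(p0)$origin, c(0, 0, 0))

  # header/value count mismatch is caught
  writeLines(head(readLines(file.path(td, "g.cube")), -10),
             file.path(td, "trunc.cube"))
  expect_error(read_grid_cube(file.path(td, "trunc.cube")), "values")
})
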