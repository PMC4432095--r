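test_that("isosurface vertices of |r| lie within one voxel diagonal of r = 1", {
  g <- abs_r_grid(33L)
  m <- isosurface(g, 1.0)
  expect_gt(nrow(m$vertices), 100L)
  rad <- sqrt(rowSums(m$vertices^2))
  h <- sqrt(3) * 4 / 32
  expect_true(all(rad >= 1 - h & rad <= 1 + h))
  expect_equal(euler_characteristic(m), 2L)      # closed sphere
  expect_equal(nrow(isosurface(g, 10)$vertices), 0L)   # out of range
  expect_error(isosurface(scalar_grid(c(0, 0, 0), diag(3),
                                      array(0, c(1, 2, 2))), 0.5),
               "at least 2")
})

test_that("sign symmetry: isosurface(g, v) equals isosurface(-g, -v)", {
  g <- abs_r_grid(17L)
  gneg <- scalar_grid(g$origin, g$axes, -g$values)
  m1 <- isosurface(g, 1.2)
  m2 <- isosurface(gneg, -1.2)
  expect_equal(nrow(m1$vertices), nrow(m2$vertices))
  expect_lt(set_match_distance(m1$vertices, m2$vertices), 1e-9)
})

test_that("signed surfaces bracket an orbital's two lobes", {
  w <- make_molecule("water")
  os <- make_orbital_set(w, list(centres = 1L, type = "pz", width = 0.8))
  pair <- signed_isosurfaces(os$grids[[1]], 0.3 * max(os$grids[[1]]$values))
  expect_gt(nrow(pair$positive$vertices), 0L)
  expect_gt(nrow(pair$negative$vertices), 0L)
  expect_true(all(pair$positive$vertices[, 3] > 0))
  expect_true(all(pair$negative$vertices[, 3] < 0))
})

test_that("combine_grids is linear and validates lattices", {
  set.seed(9)
  mk <- function() scalar_grid(c(0, 0, 0), diag(3) * 0.5,
                               array(rnorm(64), c(4, 4, 4)))
  g1 <- mk(); g2 <- mk()
  z <- combine_grids(list(g1, g1), c(1, -1))
  expect_true(all(z$values == 0))
  d2 <- combine_grids(list(g1), 2)
  expect_equal(d2$values, 2 * g1$values)
  comb <- combine_grids(list(g1, g2), c(0.3, -1.7))
  idx <- cbind(sample(4, 5, TRUE), sample(4, 5, TRUE), sample(4, 5, TRUE))
  for (r in seq_len(5))
    expect_equal(comb$values[idx[r, 1], idx[r, 2], idx[r, 3]],
                 0.3 * g1$values[idx[r, 1], idx[r, 2], idx[r, 3]] -
                   1.7 * g2$values[idx[r, 1], idx[r, 2], idx[r, 3]],
                 tolerance = 1e-12)
  # alpha + beta = total density, alpha - beta = spin density, pointwise
  a <- mk(); b <- mk()
  tot <- combine_grids(list(a, b), c(1, 1))
  spin <- combine_grids(list(a, b), c(1, -1))
  expect_equal(tot$values + spin$values, 2 * a$values, tolerance = 1e-12)

  off <- scalar_grid(c(1, 0, 0), diag(3) * 0.5, array(0, c(4, 4, 4)))
  expect_error(combine_grids(list(g1, off), c(1, 1)), "origin")
})

test_that("orbital densities integrate to their occupations", {
  w <- make_molecule("water")
  os <- make_orbital_set(w, list(centres = 1L, type = "s", width = 0.9))
  psi <- os$grids[[1]]
  # analytically normalized Gaussian: quadrature norm of psi^2 is ~1
  expect_equal(sum(psi$values^2) * abs(det(psi$axes)), 1,
               tolerance = 0.01)
  rho <- density_from_orbitals(list(psi), 2)
  expect_equal(grid_integral(rho), 2, tolerance = 0.02)
  expect_true(all(rho$values >= 0))
  zero <- density_from_orbitals(list(psi), 0)
  expect_true(all(zero$values == 0))
})

test_that("point-charge ESP matches closed forms and superposition", {
  # unit charge at the origin, evaluation at 1 bohr
  expect_equal(esp_point_charges(matrix(c(BOHR_ANGSTROM, 0, 0), 1),
                                 matrix(0, 1, 3), 1), 1, tolerance = 1e-12)
  # +/- dipole: zero on the perpendicular bisector
  cp <- rbind(c(0, 0, 1), c(0, 0, -1))
  expect_lt(abs(esp_point_charges(matrix(c(2.5, 0, 0), 1), cp,
                                  c(1, -1))), 1e-12)
  # doubling all charges doubles the potential everywhere
  set.seed(5)
  pos <- matrix(runif(30, -4, 4), ncol = 3)
  q <- runif(10, -1, 1)
  pts <- matrix(runif(21, 5, 9), ncol = 3)
  expect_equal(esp_point_charges(pts, pos, 2 * q),
               2 * esp_point_charges(pts, pos, q), tolerance = 1e-12)
  # coincident point/charge errors with indices
  expect_error(esp_point_charges(matrix(0, 1, 3), matrix(0, 1, 3), 1),
               "coincides")
})

test_that("chunked ESP equals the naive double loop", {
  set.seed(6)
  cp <- matrix(runif(300, -5, 5), ncol = 3)
  q <- runif(100, -1, 1)
  pts <- matrix(runif(150, 6, 12), ncol = 3)
  ref <- oracle_esp(pts, cp, q)
  for (chunk in c(1L, 7L, 50L, 1000L))
    expect_lt(max(abs(esp_point_charges(pts, cp, q, chunk = chunk) - ref)),
              1e-10)
})

test_that("mesh colouring evaluates the field at every vertex", {
  g <- abs_r_grid(17L)
  m <- isosurface(g, 1.0)
  const <- scalar_grid(g$origin, g$axes,
                       array(4.2, dim = g$shape))
  expect_equal(color_mesh_by_field(m, const)$vertex_scalar,
               rep(4.2, nrow(m$vertices)), tolerance = 1e-12)

  # trilinear interpolation reproduces stored values at lattice points
  set.seed(8)
  idx <- cbind(sample(17, 6), sample(17, 6), sample(17, 6))
  pts <- sweep((idx - 1) %*% g$axes, 2, g$origin, `+`)
  expect_equal(grid_interpolate(g, pts),
               g$values[idx], tolerance = 1e-12, ignore_attr = TRUE)

  # ESP colouring of a sphere mesh around +1 charge behaves as 1/r
  col <- color_mesh_by_field(m, list(positions = matrix(0, 1, 3),
                                     charges = 1))
  r_bohr <- sqrt(rowSums(m$vertices^2)) / BOHR_ANGSTROM
  expect_lt(max(abs(col$vertex_scalar - 1 / r_bohr)), 1e-9)

  # out-of-box vertices are clamped and flagged
  small <- scalar_grid(c(-0.5, -0.5, -0.5), diag(3) * 0.5,
                       array(rnorm(8), c(2, 2, 2)))
  flagged <- color_mesh_by_field(m, small)
  expect_gt(length(attr(flagged, "clamped")), 0L)
})

test_that("plane-symmetry classification separates pi from sigma", {
  w <- make_molecule("water")
  pz <- make_orbital_set(w, list(centres = 1L, type = "pz", width = 0.8))
  expect_equal(classify_plane_symmetry(pz$grids[[1]], c(0, 0, 0),
                                       c(0, 0, 1)), "pi")
  s <- make_orbital_set(w, list(centres = 1L, type = "s", width = 0.8))
  expect_equal(classify_plane_symmetry(s$grids[[1]], c(0, 0, 0),
                                       c(0, 0, 1)), "sigma")
  px <- make_orbital_set(w, list(centres = 1L, type = "px", width = 0.8))
  expect_equal(classify_plane_symmetry(px$grids[[1]], c(0, 0, 0),
                                       c(0, 0, 1)), "sigma")
  # a lone off-plane s Gaussian is neither symmetric nor antisymmetric
  off <- molecule("He", matrix(c(0, 0, 1.1), 1))
  go <- make_orbital_set(off, list(centres = 1L, type = "s", width = 0.6))
  expect_equal(classify_plane_symmetry(go$grids[[1]], c(0, 0, 0),
                                       c(0, 0, 1)), "mixed")
  zero <- scalar_grid(c(0, 0, 0), diag(3), array(0, c(3, 3, 3)))
  expect_error(classify_plane_symmetry(zero, c(0, 0, 0), c(0, 0, 1)),
               "empty orbital")
  expect_error(classify_plane_symmetry(zero, c(0, 0, 0), c(0, 0, 0)),
               "nonzero")
})
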