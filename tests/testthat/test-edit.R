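test_that("measure returns distances, angles and signed dihedrals", {
  b <- make_molecule("benzene")
  expect_equal(measure(b, c(1, 2)), 1.39, tolerance = 1e-9)

  # coplanar square, cis: zero dihedral
  sq <- molecule(rep("C", 4), rbind(c(0, 0, 0), c(1, 0, 0),
                                    c(1, 1, 0), c(0, 1, 0)))
  expect_equal(measure(sq, c(1, 2, 3, 4)), 0, tolerance = 1e-9)

  e <- make_molecule("ethane")
  expect_equal(abs(measure(e, c(3, 1, 2, 6))), 60, tolerance = 1e-9)

  lin <- molecule(rep("C", 4), cbind(0:3, 0, 0))
  expect_error(measure(lin, c(1, 2, 3, 4)), "torsion")
  expect_error(measure(b, 1), "centre")
})

test_that("dihedral sign follows the IUPAC convention", {
  # D at +60 deg counter-clockwise from A, sighting B -> C along +z
  m <- molecule(rep("C", 4),
                rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                      c(cos(pi / 3), sin(pi / 3), 1)))
  expect_equal(measure(m, c(1, 2, 3, 4)), 60, tolerance = 1e-9)
  m$xyz[4, ] <- c(cos(pi / 3), -sin(pi / 3), 1)
  expect_equal(measure(m, c(1, 2, 3, 4)), -60, tolerance = 1e-9)
})

test_that("set_internal hits its target and leaves non-movers bit-identical", {
  h2 <- make_molecule("h2")
  h <- set_internal(h2, c(1, 2), 1.0)
  expect_equal(measure(h, c(1, 2)), 1.0, tolerance = 1e-9)
  expect_identical(h$xyz[2, ], h2$xyz[2, ])

  w <- make_molecule("water")
  w2 <- set_internal(w, c(2, 1, 3), 109.47)
  expect_equal(measure(w2, c(2, 1, 3)), 109.47, tolerance = 1e-9)
  expect_identical(w2$xyz[c(1, 3), ], w$xyz[c(1, 3), ])

  e <- make_molecule("ethane")
  e2 <- set_internal(e, c(3, 1, 2, 6), -45)
  expect_equal(measure(e2, c(3, 1, 2, 6)), -45, tolerance = 1e-9)
  expect_identical(e2$xyz[-3, ], e$xyz[-3, ])
})

test_that("identity edits keep coordinates within 1e-12 and edits are idempotent", {
  e <- make_molecule("ethane")
  for (sel in list(c(1, 2), c(3, 1, 2), c(3, 1, 2, 6))) {
    cur <- measure(e, sel)
    expect_lt(max(abs(set_internal(e, sel, cur)$xyz - e$xyz)), 1e-12)
    once <- set_internal(e, sel, cur * 0.9 + 1e-3)
    twice <- set_internal(once, sel, cur * 0.9 + 1e-3)
    expect_lt(max(abs(twice$xyz - once$xyz)), 1e-12)
  }
})

test_that("group edits move the set rigidly", {
  e <- make_molecule("ethane")
  g <- mark_group(e, "side_of_bond", bond = c(1, 2), side = 1)
  e2 <- set_internal(e, c(3, 1, 2, 6), 0, group = g)
  expect_equal(measure(e2, c(3, 1, 2, 6)), 0, tolerance = 1e-9)
  pd <- function(m) as.matrix(dist(m$xyz[g$members, ]))
  expect_lt(max(abs(pd(e2) - pd(e))), 1e-9)
  others <- setdiff(seq_len(n_atoms(e)), g$members)
  expect_identical(e2$xyz[others, ], e$xyz[others, ])

  # compare against an explicit rigid-rotation oracle about the C-C axis
  delta <- (measure(e, c(3, 1, 2, 6)) - 0) * pi / 180
  u <- (e$xyz[2, ] - e$xyz[1, ]); u <- u / sqrt(sum(u^2))
  ct <- cos(delta); st <- sin(delta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  R <- ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
  rot <- sweep(sweep(e$xyz[g$members, ], 2, e$xyz[1, ]) %*% t(R),
               2, e$xyz[1, ], `+`)
  expect_lt(max(abs(e2$xyz[g$members, ] - rot)), 1e-9)

  # a group missing the mover, or containing a moved reference, errors
  expect_error(set_internal(e, c(3, 1, 2, 6), 10, group = c(4, 5)),
               "first selected")
  expect_error(set_internal(e, c(3, 1, 2, 6), 10, group = c(3, 6)),
               "fixed reference")
})

test_that("degenerate angle targets are rejected", {
  w <- make_molecule("water")
  expect_error(set_internal(w, c(2, 1, 3), 180), "between 0 and 180")
  expect_error(set_internal(w, c(2, 1, 3), 0), "between 0 and 180")
})

test_that("set_cartesian overwrites exactly one atom", {
  b <- make_molecule("benzene")
  b2 <- set_cartesian(b, 1, c(0, 0, 0))
  expect_equal(b2$xyz[1, ], c(0, 0, 0))
  expect_identical(b2$xyz[-1, ], b$xyz[-1, ])
  expect_identical(set_cartesian(b, 5, b$xyz[5, ])$xyz, b$xyz)
  b3 <- set_cartesian(b, 1, c(3, 4, 0))
  expect_equal(measure(b3, c(1, 4)),
               sqrt(sum((c(3, 4, 0) - b$xyz[4, ])^2)), tolerance = 1e-12)
  expect_error(set_cartesian(b, 99, c(0, 0, 0)), "range")
})

test_that("dummy atoms appear at midpoints and never bond", {
  b <- make_molecule("benzene")
  bd <- add_dummy(b, midpoint_of = c(1, 2))
  expect_equal(bd$xyz[13, ], (b$xyz[1, ] + b$xyz[2, ]) / 2)
  expect_identical(bd$element[13], "X")
  expect_equal(perceive_bonds(bd), perceive_bonds(b))
  bd2 <- add_dummy(b, position = c(1, 2, 3))
  expect_equal(bd2$xyz[13, ], c(1, 2, 3))
  expect_error(add_dummy(b, midpoint_of = integer(0)), "empty")
})

test_that("fragment attachment replaces hydrogens with oriented fragments", {
  b <- make_molecule("benzene")
  tol <- attach_fragment(b, 7, builtin_fragment("methyl"))
  expect_equal(n_atoms(tol), 15L)
  expect_equal(mol_formula(tol), "C7H8")
  # new methyl carbon bonded to the ring at the covalent-radii sum
  nc <- which(tol$element == "C")[7]
  expect_equal(measure(tol, c(1, nc)), 2 * covalent_radius("C"),
               tolerance = 1e-9)

  dur <- make_molecule("durene")
  expect_equal(n_atoms(dur), 24L)
  expect_equal(mol_formula(dur), "C10H14")

  # replacing an H by the H fragment at a radii-sum site is the identity
  ch <- covalent_radius("C") + covalent_radius("H")
  m <- molecule(c("C", "H", "H", "H", "H"),
                rbind(c(0, 0, 0),
                      ch / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1),
                                           c(-1, 1, -1), c(-1, -1, 1))))
  m2 <- attach_fragment(m, 2, builtin_fragment("hydrogen"))
  expect_equal(mol_formula(m2), "CH4")
  expect_lt(set_match_distance(m2$xyz, m$xyz), 1e-6)

  expect_error(attach_fragment(b, 1, builtin_fragment("methyl")),
               "hydrogen")
})

test_that("normal-mode frames follow the sine schedule", {
  w <- make_molecule("water")
  mode <- rbind(c(0, 0, -0.2), c(0.1, 0, 0.1), c(-0.1, 0, 0.1))
  tr <- normal_mode_frames(w, mode, amplitude = 0.3, nframes = 4)
  expect_equal(length(tr$frames), 4L)
  expect_identical(tr$frames[[1]], w$xyz)                # sin(0) = 0
  expect_equal(tr$frames[[2]], w$xyz + 0.3 * mode)       # sin(pi/2) = 1

  z <- normal_mode_frames(w, mode, amplitude = 0, nframes = 5)
  for (f in z$frames) expect_identical(f, w$xyz)

  # symmetric stretch keeps the two O-H distances equal in every frame
  sym <- rbind(c(0, 0, 0),
               0.1 * (w$xyz[2, ] - w$xyz[1, ]),
               0.1 * (w$xyz[3, ] - w$xyz[1, ]))
  ts <- normal_mode_frames(w, sym, amplitude = 0.25, nframes = 6)
  for (f in ts$frames) {
    d1 <- sqrt(sum((f[2, ] - f[1, ])^2))
    d2 <- sqrt(sum((f[3, ] - f[1, ])^2))
    expect_equal(d1, d2, tolerance = 1e-12)
  }
  expect_error(normal_mode_frames(w, mode[1:2, ], 0.1, 3), "per atom")
})
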