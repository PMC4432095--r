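test_that("symmetry operations are assembled from pivots by arity", {
  b <- make_molecule("benzene")
  bd <- add_dummy(b, midpoint_of = c(1, 4))   # ring centre

  inv <- make_operation(bd, 13, "inversion")
  expect_equal(inv$Q, -diag(3))
  expect_equal(apply_symop(inv, bd$xyz[1, ]), bd$xyz[4, ],
               tolerance = 1e-9)

  rot <- make_operation(b, c(1, 4), "rotation", angle = 180)
  expect_equal(det(rot$Q), 1, tolerance = 1e-12)

  ref <- make_operation(b, c(1, 2, 3), "reflection")
  expect_equal(det(ref$Q), -1, tolerance = 1e-12)
  # benzene lies in its own mirror plane
  expect_lt(max(abs(apply_symop(ref, b$xyz) - b$xyz)), 1e-9)

  tr <- make_operation(b, c(1, 4), "translation", multiple = 2)
  expect_equal(apply_symop(tr, b$xyz[1, ]),
               b$xyz[1, ] + 2 * (b$xyz[4, ] - b$xyz[1, ]))

  expect_error(make_operation(b, c(1, 2), "inversion"), "1 pivot")
  expect_error(make_operation(b, c(1, 2, 3), "rotation", angle = 90),
               "2 pivot")
  lin <- molecule(rep("C", 3), cbind(0:2, 0, 0))
  expect_error(make_operation(lin, c(1, 2, 3), "reflection"), "collinear")
  two <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(make_operation(two, c(1, 2), "rotation", angle = 10),
               "coincident")
})

test_that("rotations of order n return to the identity after n steps", {
  b <- make_molecule("benzene")
  bd <- add_dummy(b, position = c(0, 0, 0))
  bd <- add_dummy(bd, position = c(0, 0, 1))
  for (n in c(2, 3, 6)) {
    op <- make_operation(bd, c(13, 14), "rotation", angle = 360 / n)
    M <- diag(3)
    for (k in seq_len(n)) M <- op$Q %*% M
    expect_lt(max(abs(M - diag(3))), 1e-9)
  }
})

test_that("every operation is an isometry on the replicated images", {
  set.seed(4)
  w <- make_molecule("water")
  wd <- add_dummy(w, position = c(1.2, -0.3, 0.8))
  ops <- list(make_operation(wd, 4, "inversion"),
              make_operation(wd, c(1, 4), "rotation", angle = 73),
              make_operation(wd, c(1, 2, 3), "reflection"),
              make_operation(wd, c(1, 4), "translation"))
  for (op in ops) {
    img <- apply_symop(op, w$xyz)
    expect_lt(max(abs(dist(img) - dist(w$xyz))), 1e-9)
  }
})

test_that("replication merges close images in average position", {
  # identity rotation: every image merges, atom count unchanged
  b <- make_molecule("benzene")
  op <- make_operation(b, c(1, 4), "rotation", angle = 360)
  expect_equal(n_atoms(apply_replicate(b, op, threshold = 0.3)), 12L)

  # translation of an isolated tetrahedron: no merges, count doubles
  s <- make_molecule("sio4")
  sd <- add_dummy(s, position = c(0, 0, 0))
  sd <- add_dummy(sd, position = c(8, 0, 0))
  tr <- make_operation(sd, c(6, 7), "translation")
  expect_equal(n_atoms(apply_replicate(s, tr, threshold = 0.3)), 10L)

  # merging different elements is a symmetry clash
  hcl <- molecule(c("H", "Cl"), rbind(c(0, 0, 0), c(1.3, 0, 0)))
  hd <- add_dummy(hcl, midpoint_of = c(1, 2))
  inv <- make_operation(hd, 3, "inversion")
  expect_error(apply_replicate(hcl, inv, threshold = 0.5), "clash")
})

test_that("closure under repeated Cn replication is reached with count <= n * n0", {
  w <- make_molecule("water")   # C2 axis along z through the oxygen
  wd <- add_dummy(w, position = w$xyz[1, ] + c(0, 0, -1))
  op <- make_operation(wd, c(1, 4), "rotation", angle = 120)
  mol <- w
  for (k in 1:3) mol <- apply_replicate(mol, op, threshold = 0.3)
  expect_lte(n_atoms(mol), 3L * n_atoms(w))
  img <- apply_symop(op, mol$xyz)
  expect_lt(set_match_distance(img, mol$xyz), 1e-6)
})

test_that("the naphthalene build gives 18 atoms by two equivalent routes", {
  naph <- build_naphthalene_rotation()
  expect_equal(n_atoms(naph), 18L)
  expect_equal(mol_formula(naph), "C10H8")

  naph2 <- build_naphthalene_inversion()
  expect_equal(n_atoms(naph2), 18L)
  expect_lt(set_match_distance(naph$xyz, naph2$xyz), 1e-6)
})

test_that("symmetrize enforces the operation and is idempotent", {
  b <- make_molecule("benzene")
  bb <- set_cartesian(b, 1, b$xyz[1, ] + c(0, 0, 0.05))
  op <- make_operation(bb, c(2, 3, 4), "reflection")
  bs <- symmetrize(bb, op, threshold = 0.3)
  expect_lt(max(abs(bs$xyz[, 3])), 1e-9)                  # coplanar
  expect_lt(max(abs(apply_symop(op, bs$xyz) - bs$xyz)), 1e-9)

  # idempotent, and a fixed point on an already-symmetric molecule
  expect_lt(max(abs(symmetrize(bs, op)$xyz - bs$xyz)), 1e-12)
  expect_lt(max(abs(symmetrize(b, op)$xyz - b$xyz)), 1e-12)

  # atoms with no partner within threshold are reported untouched
  far <- add_atoms(bb, "C", matrix(c(0, 0, 9), 1))
  fs <- symmetrize(far, op, threshold = 0.3)
  expect_true(n_atoms(far) %in% attr(fs, "unmatched"))
  expect_identical(fs$xyz[n_atoms(far), ], far$xyz[n_atoms(far), ])

  expect_error(symmetrize(b, make_operation(b, c(1, 4), "rotation",
                                            angle = 120)), "two-fold")
})

test_that("point groups are detected for the reference geometries", {
  expect_equal(detect_point_group(make_molecule("benzene"))$schoenflies,
               "D6h")
  expect_equal(detect_point_group(make_molecule("water"))$schoenflies,
               "C2v")
  expect_equal(detect_point_group(make_molecule("methane"))$schoenflies,
               "Td")
  expect_equal(detect_point_group(make_molecule("ethane"))$schoenflies,
               "D3d")
  single <- molecule("Ar", matrix(0, 1, 3))
  expect_equal(detect_point_group(single)$schoenflies, "Kh")
  lin <- molecule(c("O", "C", "O"),
                  rbind(c(-1.16, 0, 0), c(0, 0, 0), c(1.16, 0, 0)))
  expect_equal(detect_point_group(lin)$schoenflies, "Dinfh")
  asym <- molecule(c("C", "H", "O", "N"),
                   rbind(c(0, 0, 0), c(1.1, 0, 0), c(0, 1.3, 0.2),
                         c(-0.7, -0.4, 1.0)))
  expect_equal(detect_point_group(asym)$schoenflies, "C1")
})

test_that("every reported element maps the molecule onto itself", {
  for (name in c("benzene", "water", "methane")) {
    mol <- make_molecule(name)
    m <- atomic_mass(mol$element)
    ctr <- colSums(mol$xyz * m) / sum(m)
    X <- sweep(mol$xyz, 2, ctr)
    pg <- detect_point_group(mol)
    for (i in seq_len(nrow(pg$elements))) {
      e <- pg$elements[i, ]
      Q <- if (e$kind == "rotation") {
        u <- c(e$x, e$y, e$z); u <- u / sqrt(sum(u^2))
        th <- 2 * pi / e$order
        ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                     3, 3, byrow = TRUE)
        cos(th) * diag(3) + sin(th) * ux + (1 - cos(th)) * (u %o% u)
      } else if (e$kind == "reflection") {
        u <- c(e$x, e$y, e$z); u <- u / sqrt(sum(u^2))
        diag(3) - 2 * (u %o% u)
      } else -diag(3)
      img <- X %*% t(Q)
      # brute-force: each image must coincide with a same-element atom
      for (a in seq_len(nrow(X))) {
        d <- sqrt(rowSums(sweep(X, 2, img[a, ])^2))
        d[mol$element != mol$element[a]] <- Inf
        expect_lt(min(d), pg$tol)
      }
    }
  }
})

test_that("point-group labels are invariant under rigid motion", {
  set.seed(21)
  for (name in c("benzene", "water", "methane")) {
    ref <- detect_point_group(make_molecule(name))$schoenflies
    for (k in 1:3) {
      moved <- random_rigid(make_molecule(name))
      expect_equal(detect_point_group(moved)$schoenflies, ref,
                   info = name)
    }
  }
})
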