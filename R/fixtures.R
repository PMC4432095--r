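# Deterministic generators for test systems: idealized small molecules,
# layered calcium-silicate slabs with point charges, analytic Gaussian
# orbital grids and dipolar water droplets.  Every generator is a pure
# function of its parameters (and an explicit seed where randomness is
# involved), so fixtures are reproducible bit for bit.

#' Idealized reference molecules
#'
#' Constructed geometries: `benzene` (regular hexagon, C-C 1.39, C-H
#' 1.09, planar, in the z = 0 plane), `water` (O-H 0.9572, angle
#' 104.52), `ethane` (staggered, C-C 1.536, C-H 1.09), `methane`
#' (tetrahedral, C-H 1.09), `h2` (0.74), `sio4` (regular tetrahedron,
#' Si-O 1.62), `sio4_dimer` (two corner-sharing tetrahedra) and `durene`
#' (1,2,4,5-tetramethylbenzene, built by repeated methyl attachment on
#' benzene).
#'
#' @param name fixture name.
#' @return a molecule.
#' @export
make_molecule <- function(name = c("benzene", "water", "ethane",
                                   "methane", "h2", "sio4", "sio4_dimer",
                                   "durene")) {
  name <- match.arg(name)
  switch(name,
    h2 = molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)),
                  metadata = list(title = "h2")),
    water = {
      # O at origin, H's in the xz plane, C2 axis along z
      r <- 0.9572; half <- rad(104.52 / 2)
      molecule(c("O", "H", "H"),
               rbind(c(0, 0, 0),
                     c(r * sin(half), 0, r * cos(half)),
                     c(-r * sin(half), 0, r * cos(half))),
               metadata = list(title = "water"))
    },
    benzene = {
      ang <- rad(seq(0, 300, by = 60))
      rc <- 1.39; rh <- 1.39 + 1.09
      xyz <- rbind(cbind(rc * cos(ang), rc * sin(ang), 0),
                   cbind(rh * cos(ang), rh * sin(ang), 0))
      molecule(c(rep("C", 6), rep("H", 6)), xyz,
               metadata = list(title = "benzene"))
    },
    ethane = {
      d <- 1.536; dch <- 1.09; th <- rad(180 - 111.17)
      up <- vapply(c(90, 210, 330), function(phi)
        c(dch * sin(th) * cos(rad(phi)), dch * sin(th) * sin(rad(phi)),
          d / 2 + dch * cos(th)), numeric(3))
      dn <- vapply(c(30, 150, 270), function(phi)
        c(dch * sin(th) * cos(rad(phi)), dch * sin(th) * sin(rad(phi)),
          -d / 2 - dch * cos(th)), numeric(3))
      molecule(c("C", "C", rep("H", 6)),
               rbind(c(0, 0, d / 2), c(0, 0, -d / 2), t(up), t(dn)),
               metadata = list(title = "ethane"))
    },
    methane = {
      d <- 1.09 / sqrt(3)
      molecule(c("C", rep("H", 4)),
               rbind(c(0, 0, 0), d * rbind(c(1, 1, 1), c(1, -1, -1),
                                           c(-1, 1, -1), c(-1, -1, 1))),
               metadata = list(title = "methane"))
    },
    sio4 = {
      d <- 1.62 / sqrt(3)
      molecule(c("Si", rep("O", 4)),
               rbind(c(0, 0, 0), d * rbind(c(1, 1, 1), c(1, -1, -1),
                                           c(-1, 1, -1), c(-1, -1, 1))),
               metadata = list(title = "sio4"))
    },
    sio4_dimer = {
      t1 <- make_molecule("sio4")
      # share the O along (1,1,1): mirror the tetrahedron through it
      o_shared <- t1$xyz[2, ]
      op <- sym_op("inversion", -diag(3), 2 * o_shared)
      apply_replicate(t1, op, threshold = 0.3)
    },
    durene = {
      mol <- make_molecule("benzene")
      frag <- builtin_fragment("methyl")
      # methyls at ring positions 1, 2, 4, 5; the H on ring carbon k has
      # id k + 6, and ids compact after each deletion
      for (pos in c(1L, 2L, 4L, 5L)) {
        h <- which(mol$element == "H")[pos]
        mol <- attach_fragment(mol, h, frag)
      }
      mol$metadata$title <- "durene"
      mol
    })
}

#' Layered Ca/Si/O platelet with point charges
#'
#' A calcium-silicate slab grown from a 13-atom Ca2Si3O8 motif by
#' translation symmetry operations on a thin (wide x wide x few) cell
#' grid, trimmed to exactly `n_atoms`.  Charges are drawn per element
#' (Ca +1.5, Si +1.8, O -1.1, each +/- 0.2 uniform) with the given seed
#' and then shifted so the net charge is exactly zero.
#'
#' @param n_atoms total atom count (e.g. 9360).
#' @param seed integer seed for the charge noise.
#' @return a molecule with per-atom charges.
#' @export
make_platelet <- function(n_atoms, seed = 1L) {
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 1L) stop("n_atoms must be >= 1", call. = FALSE)
  a <- 5.6; b <- 5.6; cc <- 4.8   # cell edges, angstrom
  motif_el <- c("Ca", "Ca", "Si", "Si", "Si", rep("O", 8))
  motif_xyz <- rbind(
    c(0.7, 0.7, 2.4), c(3.5, 3.5, 2.4),
    c(1.4, 3.9, 0.8), c(3.9, 1.4, 0.8), c(2.65, 2.65, 3.6),
    c(0.3, 2.6, 0.6), c(2.6, 0.3, 0.6), c(1.9, 4.9, 2.0),
    c(4.9, 1.9, 2.0), c(1.6, 1.6, 4.2), c(3.7, 3.7, 4.3),
    c(0.8, 4.2, 3.4), c(4.2, 0.8, 3.4))
  per_cell <- length(motif_el)
  ncell <- ceiling(n_atoms / per_cell)
  # thin platelet: nz layers fixed at 5 (or fewer), grow laterally
  nz <- min(5L, ncell)
  nxy <- ceiling(sqrt(ncell / nz))
  mol <- molecule(motif_el, motif_xyz)
  mol <- grow_translations(mol, c(a, 0, 0), nxy)
  mol <- grow_translations(mol, c(0, b, 0), nxy)
  mol <- grow_translations(mol, c(0, 0, cc), nz)
  if (n_atoms > n_atoms(mol))
    stop("internal: slab too small", call. = FALSE)
  if (n_atoms < n_atoms(mol))
    mol <- delete_atoms(mol, seq(n_atoms + 1L, n_atoms(mol)))
  base <- c(Ca = 1.5, Si = 1.8, O = -1.1)
  q <- with_preserved_seed(as.integer(seed), function()
    base[mol$element] + stats::runif(n_atoms(mol), -0.2, 0.2))
  q <- q - mean(q)   # enforce zero net charge
  mol$charge <- unname(q)
  mol$metadata$title <- sprintf("platelet_%d", n_atoms)
  attr(mol, "id_map") <- NULL
  mol
}

# replicate a molecule n-fold along a lattice vector by repeated
# translation operations (threshold 0: pure replication, no merging)
grow_translations <- function(mol, vec, n) {
  if (n <= 1L) return(mol)
  n0 <- n_atoms(mol)
  pivot <- molecule(c(DUMMY, DUMMY), rbind(c(0, 0, 0), vec))
  for (k in seq_len(n - 1L)) {
    op <- make_operation(pivot, c(1L, 2L), "translation", multiple = k)
    mol <- apply_replicate(mol, op, targets = seq_len(n0), threshold = 0)
  }
  mol
}

#' Analytic Gaussian orbital grids for a molecule
#'
#' Builds atom-centred Gaussian orbitals on one shared lattice:
#' `s`-type `exp(-r^2/w^2)` (even under any reflection through the atom)
#' and `p`-type `(x_k - c_k) exp(-r^2/w^2)` (odd along the chosen axis).
#' The `durene_like` spec emulates an orbital list for the durene
#' molecule: 6 pi combinations (Hueckel-style pz patterns over the six
#' ring carbons) plus 12 sigma orbitals (s and in-plane p combinations),
#' with plausible energies and occupations.
#'
#' @param geometry a molecule (taken as lying in the z = 0 plane for
#'   `durene_like`).
#' @param spec `"durene_like"`, or a list with fields `centres` (atom
#'   ids), `type` (`"s"`/`"px"`/`"py"`/`"pz"`), `width`.
#' @param spacing lattice step, angstrom (<= 0.5 to resolve parity).
#' @param padding box padding beyond the atoms, angstrom.
#' @return an [orbital_set()] whose grids share one lattice.
#' @export
make_orbital_set <- function(geometry, spec = "durene_like",
                             spacing = 0.35, padding = 3.0) {
  if (spacing > 0.5)
    warning("lattice step > 0.5 angstrom may be too coarse to resolve parity")
  lat <- symmetric_lattice(geometry, spacing, padding)
  pts <- grid_coordinates_raw(lat)
  gauss <- function(centre, width, type = "s") {
    r2 <- rowSums(sweep(pts, 2, centre, `-`)^2)
    g <- exp(-r2 / width^2)
    pre <- switch(type, s = 1, px = pts[, 1] - centre[1],
                  py = pts[, 2] - centre[2], pz = pts[, 3] - centre[3])
    pre * g
  }
  # analytic L2 normalization for a single Gaussian of the given type
  analytic_norm <- function(width, type) {
    alpha <- 1 / width^2
    if (type == "s") (2 * alpha / pi)^0.75
    else (2 * alpha / pi)^0.75 * 2 * sqrt(alpha)
  }
  as_grid <- function(v, label, nrm = NULL) {
    if (is.null(nrm)) nrm <- sqrt(sum(v^2) * abs(det(lat$axes)))
    scalar_grid(lat$origin, lat$axes, array(v / nrm, dim = lat$shape),
                label = label)
  }
  if (identical(spec, "durene_like")) {
    ring <- which(geometry$element == "C")[1:6]
    w <- 0.9
    ao_pz <- lapply(ring, function(i) gauss(geometry$xyz[i, ], w, "pz"))
    ao_s <- lapply(ring, function(i) gauss(geometry$xyz[i, ], w, "s"))
    ao_px <- lapply(ring, function(i) gauss(geometry$xyz[i, ], w, "px"))
    # the six real ring-mode coefficient patterns over positions k = 0..5
    k <- 0:5
    cf <- list(rep(1, 6), cos(pi * k / 3), sin(pi * k / 3),
               cos(2 * pi * k / 3), sin(2 * pi * k / 3), (-1)^k)
    combo <- function(aos, coef) Reduce(`+`, Map(`*`, aos, coef))
    grids <- c(
      lapply(1:6, function(m) as_grid(combo(ao_s, cf[[m]]),
                                      sprintf("sigma_s_%d", m))),
      lapply(1:6, function(m) as_grid(combo(ao_px, cf[[m]]),
                                      sprintf("sigma_p_%d", m))),
      lapply(1:6, function(m) as_grid(combo(ao_pz, cf[[m]]),
                                      sprintf("pi_%d", m))))
    energy <- c(seq(-1.10, -0.85, length.out = 6),   # sigma (s)
                seq(-0.80, -0.55, length.out = 6),   # sigma (p)
                c(-0.35, -0.30, -0.30, 0.15, 0.15, 0.40))  # pi
    occupation <- c(rep(2, 12), 2, 2, 2, 0, 0, 0)
    rec <- orbital_records(index = 1:18, symmetry = "a",
                           energy = energy, occupation = occupation,
                           subspace = ifelse(occupation > 0, "inactive",
                                             "secondary"),
                           grid = 1:18)
    orbital_set(rec, grids)
  } else {
    w <- spec$width %||% 0.9
    grids <- lapply(seq_along(spec$centres), function(i) {
      ty <- spec$type[i] %||% "s"
      as_grid(gauss(geometry$xyz[spec$centres[i], ], w, ty),
              sprintf("%s_%d", ty, i),
              nrm = 1 / analytic_norm(w, ty))
    })
    rec <- orbital_records(index = seq_along(grids), grid = seq_along(grids))
    orbital_set(rec, grids)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# orthogonal lattice covering the molecule plus padding, arranged so that
# z = 0 is exactly a lattice mirror plane (parity checks are then exact)
symmetric_lattice <- function(mol, spacing, padding) {
  lo <- apply(mol$xyz, 2, min) - padding
  hi <- apply(mol$xyz, 2, max) + padding
  zmax <- max(abs(c(lo[3], hi[3])))
  nxy <- ceiling((hi[1:2] - lo[1:2]) / spacing) + 1L
  nzh <- ceiling(zmax / spacing)
  shape <- c(nxy, 2L * nzh + 1L)
  origin <- c(lo[1:2], -nzh * spacing)
  list(origin = origin, axes = diag(rep(spacing, 3)), shape = shape)
}

grid_coordinates_raw <- function(lat) {
  idx <- as.matrix(expand.grid(ix = seq_len(lat$shape[1]) - 1,
                               iy = seq_len(lat$shape[2]) - 1,
                               iz = seq_len(lat$shape[3]) - 1))
  sweep(idx %*% lat$axes, 2, lat$origin, `+`)
}

#' Promolecule density grid
#'
#' A synthetic electron-density stand-in: a sum of spherical Gaussian
#' atomic densities (height = atomic number, width proportional to the
#' covalent radius), evaluated on an orthogonal lattice over the
#' molecule's bounding box.  Contributions are accumulated per atom over
#' a local sub-block only, so large systems stay cheap.
#'
#' @param mol a molecule.
#' @param shape lattice shape (length-3 integer, e.g. `c(64, 64, 64)`).
#' @param padding box padding, angstrom.
#' @param cutoff per-atom evaluation radius, angstrom.
#' @param width_scale Gaussian width as a multiple of the covalent radius;
#'   the default 1.1 gives a smooth molecular envelope rather than
#'   per-atom bumps.
#' @return a [scalar_grid()] with `molecule` attached.
#' @export
promolecule_density <- function(mol, shape = c(64L, 64L, 64L),
                                padding = 3.0, cutoff = 4.0,
                                width_scale = 1.1) {
  real <- which(!is_dummy_symbol(mol$element))
  lo <- apply(mol$xyz[real, , drop = FALSE], 2, min) - padding
  hi <- apply(mol$xyz[real, , drop = FALSE], 2, max) + padding
  shape <- as.integer(shape)
  step <- (hi - lo) / (shape - 1L)
  vals <- array(0, dim = shape)
  width <- width_scale * covalent_radius(mol$element[real])
  height <- atomic_number(mol$element[real])
  for (t in seq_along(real)) {
    ctr <- mol$xyz[real[t], ]
    i0 <- pmax(ceiling((ctr - cutoff - lo) / step), 0)
    i1 <- pmin(floor((ctr + cutoff - lo) / step), shape - 1L)
    if (any(i0 > i1)) next
    ix <- seq(i0[1], i1[1]); iy <- seq(i0[2], i1[2]); iz <- seq(i0[3], i1[3])
    dx2 <- (lo[1] + ix * step[1] - ctr[1])^2
    dy2 <- (lo[2] + iy * step[2] - ctr[2])^2
    dz2 <- (lo[3] + iz * step[3] - ctr[3])^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    vals[ix + 1L, iy + 1L, iz + 1L] <-
      vals[ix + 1L, iy + 1L, iz + 1L] +
      height[t] * exp(-r2 / width[t]^2)
  }
  g <- scalar_grid(lo, diag(step), vals, label = "promolecule density")
  g$molecule <- mol
  g
}

#' Water droplet snapshot with per-molecule dipoles
#'
#' `n` water molecules at non-overlapping positions (minimum centre
#' separation 2.5 angstrom) inside a sphere, each with a random
#' orientation and a dipole of 1.85 debye along its C2 axis.  Emulates a
#' Monte Carlo snapshot of a dipolar (Stockmayer-type) water droplet;
#' no simulation is performed.
#'
#' @param n_molecules number of water molecules.
#' @param radius droplet radius, angstrom.
#' @param seed integer seed.
#' @return a molecule whose metadata carries `molecule_dipoles` (n x 3,
#'   debye) and `molecule_index` (per atom).
#' @export
make_droplet <- function(n_molecules, radius = 20, seed = 1L) {
  water <- make_molecule("water")
  res <- with_preserved_seed(as.integer(seed), function() {
    centres <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(centres) < n_molecules) {
      tries <- tries + 1L
      if (tries > 200L * n_molecules)
        stop("cannot pack ", n_molecules, " molecules in radius ", radius,
             call. = FALSE)
      p <- stats::runif(3, -radius, radius)
      if (vnorm(p) > radius) next
      if (nrow(centres) > 0 &&
          min(sqrt(rowSums(sweep(centres, 2, p, `-`)^2))) < 2.5) next
      centres <- rbind(centres, p)
    }
    axes <- matrix(stats::rnorm(3 * n_molecules), ncol = 3)
    rolls <- stats::runif(n_molecules, 0, 360)
    list(centres = centres, axes = axes, rolls = rolls)
  })
  el <- character(0); xyz <- matrix(0, 0, 3); idx <- integer(0)
  dip <- matrix(0, n_molecules, 3)
  for (k in seq_len(n_molecules)) {
    u <- unitv(res$axes[k, ])
    R2 <- rotation_matrix(u, res$rolls[k])
    R1 <- rotation_between(c(0, 0, 1), u)
    w <- sweep(water$xyz %*% t(R1) %*% t(R2), 2, res$centres[k, ], `+`)
    el <- c(el, water$element)
    xyz <- rbind(xyz, w)
    idx <- c(idx, rep(k, 3L))
    dip[k, ] <- 1.85 * u   # along the molecular C2 axis
  }
  molecule(el, xyz,
           metadata = list(title = sprintf("droplet_%d", n_molecules),
                           molecule_dipoles = as.numeric(dip),
                           molecule_index = idx))
}
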