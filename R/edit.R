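# Editing in ad-hoc internal coordinates.
#
# Geometry is stored in Cartesian coordinates but edited through transient
# internal coordinates defined by an ordered atom selection (a partial
# Z-matrix created on the fly): 2 atoms define a distance, 3 a valence
# angle, 4 a torsion.  The first selected atom is the mover; optionally a
# whole group moves rigidly with it.  Atoms outside the moving set are
# never touched.

#' Measure an internal coordinate
#'
#' Arity 2 gives the Euclidean distance (angstrom); arity 3 the valence
#' angle at the middle atom (degrees, in `[0, 180]`); arity 4 the signed
#' dihedral A-B-C-D in `(-180, 180]`, positive when, sighting from B to C,
#' the rotation carrying A onto D is counter-clockwise.
#'
#' @param mol a molecule.
#' @param selection a [select_atoms()] selection of arity 2-4 (a plain id
#'   vector is accepted).
#' @return the measured value (angstrom or degrees).
#' @export
measure <- function(mol, selection) {
  sel <- as_selection(mol, selection)
  p <- lapply(sel$ids, function(i) mol$xyz[i, ])
  switch(sel$focus,
    distance = {
      d <- vnorm(p[[1]] - p[[2]])
      if (d < 1e-9) stop("coincident points", call. = FALSE)
      d
    },
    angle = angle_deg(p[[1]], p[[2]], p[[3]]),
    torsion = dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]]),
    stop("cannot measure a single centre", call. = FALSE))
}

as_selection <- function(mol, selection) {
  if (inherits(selection, "mol_selection")) return(selection)
  select_atoms(mol, selection)
}

#' Set an internal coordinate
#'
#' Moves the first selected atom (or, with `group`, a rigid set containing
#' it) so the selected internal coordinate takes `value`:
#' * distance: translation along the line joining the two selected atoms;
#' * angle: rotation about the axis through the vertex atom normal to the
#'   selection plane;
#' * torsion: rotation about the B-C axis.
#'
#' All atoms outside the moving set keep bit-identical positions, and
#' re-measuring returns `value` to within 1e-9.  A target angle of exactly
#' 180 degrees is rejected (the rotation plane would be arbitrary).
#'
#' @param mol a molecule.
#' @param selection arity 2-4 selection (or id vector); the first atom is
#'   the mover.
#' @param value target value: angstrom for distances, degrees for angles
#'   and torsions.
#' @param group optional [mark_group()] group (or id vector) moved rigidly
#'   with the first selected atom; it must contain the mover and none of
#'   the fixed reference atoms.
#' @return the edited molecule.
#' @export
set_internal <- function(mol, selection, value, group = NULL) {
  sel <- as_selection(mol, selection)
  if (!is.finite(value)) stop("target value must be finite", call. = FALSE)
  movers <- sel$ids[1]
  fixed_in_group <- integer(0)
  if (!is.null(group)) {
    members <- if (inherits(group, "mol_group")) group$members
               else as.integer(group)
    if (!(sel$ids[1] %in% members))
      stop("group must contain the first selected atom", call. = FALSE)
    fixed_in_group <- intersect(sel$ids[-1], members)
    movers <- members
  }
  p <- lapply(sel$ids, function(i) mol$xyz[i, ])
  xyz <- mol$xyz
  if (sel$focus == "distance") {
    if (value <= 0) stop("distance must be positive", call. = FALSE)
    d <- vnorm(p[[1]] - p[[2]])
    if (d < 1e-9) stop("coincident points", call. = FALSE)
    delta <- (value - d) * unitv(p[[1]] - p[[2]])
    xyz[movers, ] <- sweep(xyz[movers, , drop = FALSE], 2, delta, `+`)
  } else if (sel$focus == "angle") {
    if (value <= 0 || value >= 180)
      stop("angle must lie strictly between 0 and 180 degrees",
           call. = FALSE)
    cur <- angle_deg(p[[1]], p[[2]], p[[3]])
    n <- crossv(p[[1]] - p[[2]], p[[3]] - p[[2]])
    if (vnorm(n) < 1e-9)
      stop("collinear atoms: rotation plane undefined", call. = FALSE)
    # right-hand rotation about n = BA x BC decreases the angle
    R <- rotation_matrix(n, cur - value)
    xyz[movers, ] <- rotate_about(xyz[movers, , drop = FALSE], R, p[[2]])
  } else if (sel$focus == "torsion") {
    cur <- dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]])
    u <- p[[3]] - p[[2]]
    # right-hand rotation of the A side about u_BC decreases the dihedral
    R <- rotation_matrix(u, cur - value)
    xyz[movers, ] <- rotate_about(xyz[movers, , drop = FALSE], R, p[[2]])
  } else stop("cannot set a single centre; use set_cartesian", call. = FALSE)
  # a fixed reference atom may sit in the mover group only if the
  # transform leaves it in place (e.g. an atom on the rotation axis)
  if (length(fixed_in_group) > 0L &&
      max(abs(xyz[fixed_in_group, , drop = FALSE] -
              mol$xyz[fixed_in_group, , drop = FALSE])) > 1e-9)
    stop("mover group contains a fixed reference atom", call. = FALSE)
  mol$xyz <- xyz
  sync_frame1(mol)
}

rotate_about <- function(xyz, R, origin) {
  sweep(sweep(xyz, 2, origin, `-`) %*% t(R), 2, origin, `+`)
}

#' Overwrite a Cartesian position
#'
#' @param mol a molecule.
#' @param id atom id.
#' @param position length-3 numeric, angstrom.
#' @export
set_cartesian <- function(mol, id, position) {
  id <- as.integer(id)
  if (id < 1L || id > n_atoms(mol)) stop("atom id out of range", call. = FALSE)
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position)))
    stop("position must be a finite length-3 vector", call. = FALSE)
  mol$xyz[id, ] <- position
  sync_frame1(mol)
}

#' Add a dummy pivot atom
#'
#' Appends a dummy atom either at an explicit position or at the arithmetic
#' mean of a selection's atom positions (e.g. the midpoint of a bond).
#' Dummy atoms never participate in perceived bonds.
#'
#' @param mol a molecule.
#' @param position explicit length-3 position (angstrom).
#' @param midpoint_of selection or id vector whose mean position is used
#'   instead.
#' @return the extended molecule; the new dummy has id `n_atoms(mol)`.
#' @export
add_dummy <- function(mol, position = NULL, midpoint_of = NULL) {
  if (is.null(position)) {
    if (is.null(midpoint_of))
      stop("give a position or a selection", call. = FALSE)
    ids <- if (inherits(midpoint_of, "mol_selection")) midpoint_of$ids
           else as.integer(midpoint_of)
    if (length(ids) == 0L) stop("empty selection for midpoint", call. = FALSE)
    position <- colMeans(mol$xyz[ids, , drop = FALSE])
  }
  add_atoms(mol, DUMMY, matrix(position, 1))
}

#' Replace a hydrogen by a molecular fragment
#'
#' The site hydrogen (bonded to exactly one heavy atom P) is deleted; the
#' fragment's link atom is placed along the former P->H direction at the
#' sum of the covalent radii of P and the link atom.  The fragment is
#' oriented by aligning its attachment axis (minus the mean of the unit
#' bond vectors at the link atom) with the direction back towards P; the
#' residual roll is fixed deterministically by placing the fragment's
#' declared reference atom anti-periplanar to the lowest-id heavy
#' neighbour of P.
#'
#' @param mol a molecule.
#' @param site id of the hydrogen atom being replaced.
#' @param fragment a molecule whose `metadata` declares `link` (attachment
#'   atom id) and optionally `ref` (roll reference atom id); see
#'   [builtin_fragment()] and [load_fragment()].
#' @param scale bond-perception scale.
#' @return the combined molecule (dummy atoms in the fragment are dropped).
#' @export
attach_fragment <- function(mol, site, fragment, scale = 1.2) {
  site <- as.integer(site)
  if (mol$element[site] != "H")
    stop("attachment site must be a hydrogen atom", call. = FALSE)
  bonds <- perceive_bonds(mol, scale)
  nb <- c(bonds[bonds[, 1] == site, 2], bonds[bonds[, 2] == site, 1])
  if (length(nb) != 1L)
    stop("site hydrogen must have exactly one bond", call. = FALSE)
  P <- nb[1]
  dirPH <- unitv(mol$xyz[site, ] - mol$xyz[P, ])
  link <- fragment$metadata$link
  if (is.null(link)) stop("fragment declares no link atom", call. = FALSE)
  link <- as.integer(link)
  ref <- fragment$metadata$ref
  fxyz <- fragment$xyz
  # attachment axis: the missing-valence direction at the link atom
  fbonds <- perceive_bonds(fragment, scale)
  lnb <- c(fbonds[fbonds[, 1] == link, 2], fbonds[fbonds[, 2] == link, 1])
  if (length(lnb) > 0L) {
    uv <- t(apply(fxyz[lnb, , drop = FALSE], 1,
                  function(x) unitv(x - fxyz[link, ])))
    axis <- -colSums(uv)
    if (vnorm(axis) > 1e-8) {
      axis <- unitv(axis)
      R <- rotation_between(axis, -dirPH)
      fxyz <- rotate_about(fxyz, R, fxyz[link, ])
    }
  }
  dist <- covalent_radius(mol$element[P]) +
    covalent_radius(fragment$element[link])
  target <- mol$xyz[P, ] + dist * dirPH
  fxyz <- sweep(fxyz, 2, target - fxyz[link, ], `+`)
  # deterministic roll: declared reference atom anti-periplanar to the
  # lowest-id heavy neighbour of P
  heavy <- c(bonds[bonds[, 1] == P, 2], bonds[bonds[, 2] == P, 1])
  heavy <- setdiff(heavy[!(mol$element[heavy] %in% c("H", DUMMY))], site)
  if (!is.null(ref) && length(heavy) > 0L) {
    ref <- as.integer(ref)
    Q <- min(heavy)
    tau <- tryCatch(
      dihedral_deg(fxyz[ref, ], fxyz[link, ], mol$xyz[P, ], mol$xyz[Q, ]),
      error = function(e) NULL)
    if (!is.null(tau)) {
      R <- rotation_matrix(fxyz[link, ] - mol$xyz[P, ], 180 - tau)
      fxyz <- rotate_about(fxyz, R, fxyz[link, ])
    }
  }
  out <- delete_atoms(mol, site)
  keep <- which(!is_dummy_symbol(fragment$element))
  out <- add_atoms(out, fragment$element[keep], fxyz[keep, , drop = FALSE],
                   fragment$charge[keep])
  if (!is.null(mol$bonds)) out$bonds <- perceive_bonds(out, scale)
  sync_frame1(out)
}

# rotation carrying unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  ax <- crossv(a, b)
  s <- vnorm(ax); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate 180 about any axis perpendicular to a
    perp <- crossv(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    return(rotation_matrix(perp, 180))
  }
  rotation_matrix(ax, deg(atan2(s, cth)))
}

#' Built-in fragment library
#'
#' Small fragments shipped with the package, each declaring `link` and
#' `ref` metadata for [attach_fragment()].
#'
#' @param name `"methyl"` or `"hydrogen"`.
#' @return a fragment molecule.
#' @export
builtin_fragment <- function(name = c("methyl", "hydrogen")) {
  name <- match.arg(name)
  switch(name,
    hydrogen = molecule("H", matrix(0, 1, 3),
                        metadata = list(link = 1L, title = "hydrogen")),
    methyl = {
      # tetrahedral CH3 with the missing valence along -z
      d <- 1.09
      th <- 180 - 109.471
      hs <- t(vapply(c(0, 120, 240), function(phi) {
        d * c(sin(rad(th)) * cos(rad(phi)),
              sin(rad(th)) * sin(rad(phi)),
              cos(rad(th)))
      }, numeric(3)))
      molecule(c("C", "H", "H", "H"), rbind(c(0, 0, 0), hs),
               metadata = list(link = 1L, ref = 2L, title = "methyl"))
    })
}

#' Load a fragment file
#'
#' Fragment files are native-dialect documents whose metadata carries the
#' reserved keys `link` and (optionally) `ref`; drop files into a directory
#' of your choice to extend the library.
#'
#' @param path path to a fragment file (`.mfx` or `.xyz`-headed dialect).
#' @return a fragment molecule.
#' @export
load_fragment <- function(path) {
  doc <- read_mfx(path)
  mol <- doc$molecule
  if (is.null(mol$metadata$link))
    stop("fragment file declares no link atom", call. = FALSE)
  mol$metadata$link <- as.integer(mol$metadata$link)
  if (!is.null(mol$metadata$ref))
    mol$metadata$ref <- as.integer(mol$metadata$ref)
  mol
}

#' Animate a normal mode as trajectory frames
#'
#' Frame k (k = 0..nframes-1) displaces the reference geometry by
#' `amplitude * sin(2*pi*k/nframes)` along the per-atom displacement
#' vectors; frame 0 is the reference geometry itself.
#'
#' @param mol a molecule.
#' @param mode n x 3 matrix of per-atom displacement vectors.
#' @param amplitude displacement amplitude, angstrom.
#' @param nframes number of frames (>= 1).
#' @return the molecule with `frames` set.
#' @export
normal_mode_frames <- function(mol, mode, amplitude, nframes) {
  mode <- matrix(as.numeric(mode), ncol = 3)
  if (nrow(mode) != n_atoms(mol))
    stop("one displacement vector per atom required", call. = FALSE)
  nframes <- as.integer(nframes)
  if (nframes < 1L) stop("nframes must be >= 1", call. = FALSE)
  mol$frames <- lapply(seq_len(nframes) - 1L, function(k)
    mol$xyz + amplitude * sin(2 * pi * k / nframes) * mode)
  mol
}
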