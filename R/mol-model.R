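# Core molecular data model: atoms (real or dummy), bonds, frames, metadata.
#
# A molecule is a list with class "molecule":
#   element  - character vector (periodic symbols, or "X" for dummy atoms)
#   xyz      - n x 3 numeric matrix, angstrom
#   charge   - numeric vector (NA when no point charge is assigned)
#   bonds    - integer m x 2 matrix (a < b), or NULL when not perceived
#   frames   - optional list of n x 3 matrices; frames[[1]] is the current
#              geometry (kept in sync by editing operations)
#   metadata - free-form named list (dipole in debye, title, energy, ...)
#
# Atom ids are 1-based row indices, stable under edits; deletions compact
# ids and report an old -> new map.

#' Construct a molecule
#'
#' @param element character vector of element symbols (`"X"` for dummy
#'   atoms).
#' @param xyz numeric n x 3 matrix of Cartesian coordinates in angstrom.
#' @param charge optional numeric vector of point charges (elementary
#'   charge units); `NA` where unassigned.
#' @param bonds optional integer two-column matrix of bonded atom-id pairs.
#' @param frames optional list of n x 3 coordinate matrices (trajectory);
#'   the first frame must equal `xyz`.
#' @param metadata named list of molecule-level metadata (e.g. `dipole`, a
#'   length-3 vector in debye; `title`; `energy`).
#' @return an object of class `"molecule"`.
#' @export
molecule <- function(element, xyz, charge = NULL, bonds = NULL,
                     frames = NULL, metadata = list()) {
  element <- as.character(element)
  check_elements(element)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- length(element)
  if (nrow(xyz) != n)
    stop("xyz must have one row per atom", call. = FALSE)
  if (n > 0 && !all(is.finite(xyz)))
    stop("non-finite coordinates", call. = FALSE)
  if (is.null(charge)) charge <- rep(NA_real_, n)
  if (length(charge) != n)
    stop("charge must have one value per atom", call. = FALSE)
  mol <- structure(list(element = element, xyz = unname(xyz),
                        charge = as.numeric(charge), bonds = NULL,
                        frames = NULL, metadata = metadata),
                   class = "molecule")
  if (!is.null(bonds)) mol$bonds <- validate_bonds(mol, bonds)
  if (!is.null(frames)) {
    frames <- lapply(frames, function(f) unname(matrix(as.numeric(f), ncol = 3)))
    if (any(vapply(frames, nrow, 0L) != n))
      stop("every frame needs one position per atom", call. = FALSE)
    if (length(frames) > 0 && max(abs(frames[[1]] - mol$xyz)) > 1e-12)
      stop("frame 1 must equal the current coordinates", call. = FALSE)
    mol$frames <- frames
  }
  mol
}

validate_bonds <- function(mol, bonds) {
  if (length(bonds) == 0L) return(matrix(integer(0), ncol = 2))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  a <- pmin(bonds[, 1], bonds[, 2]); b <- pmax(bonds[, 1], bonds[, 2])
  if (any(a < 1L) || any(b > n_atoms(mol)))
    stop("bond endpoint out of range", call. = FALSE)
  if (any(a == b)) stop("self-bond", call. = FALSE)
  if (any(is_dummy_symbol(mol$element[a])) ||
      any(is_dummy_symbol(mol$element[b])))
    stop("dummy atoms cannot be bonded", call. = FALSE)
  m <- unique(cbind(a, b))
  unname(m[order(m[, 1], m[, 2]), , drop = FALSE])
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s)", n_atoms(x), mol_formula(x)))
  if (!is.null(x$bonds)) cat(sprintf(", %d bonds", nrow(x$bonds)))
  if (!is.null(x$frames)) cat(sprintf(", %d frames", length(x$frames)))
  cat("\n")
  invisible(x)
}

#' Number of atoms (including dummies)
#' @param mol a molecule.
#' @export
n_atoms <- function(mol) length(mol$element)

#' Hill-order molecular formula
#'
#' Dummy atoms are excluded.
#' @param mol a molecule.
#' @return character scalar such as `"C10H8"`.
#' @export
mol_formula <- function(mol) {
  el <- mol$element[!is_dummy_symbol(mol$element)]
  if (length(el) == 0L) return("")
  tab <- table(el)
  syms <- names(tab)
  ord <- if ("C" %in% syms) {
    c("C", "H"[("H" %in% syms)], sort(setdiff(syms, c("C", "H"))))
  } else sort(syms)
  paste0(vapply(ord, function(s)
    paste0(s, if (tab[[s]] > 1L) tab[[s]] else ""), ""), collapse = "")
}

#' Distance-based bond perception
#'
#' Two non-dummy atoms are bonded when their separation does not exceed
#' `scale` times the sum of their covalent radii.  Deterministic and
#' invariant under rigid motion of the coordinates.
#'
#' @param mol a molecule.
#' @param scale positive multiplier for the covalent-radii sum (default
#'   1.2).
#' @return integer m x 2 matrix of bonded pairs with `a < b`.
#' @export
perceive_bonds <- function(mol, scale = 1.2) {
  stopifnot(scale > 0)
  n <- n_atoms(mol)
  real <- which(!is_dummy_symbol(mol$element))
  if (length(real) < 2L) return(matrix(integer(0), ncol = 2))
  r <- covalent_radius(mol$element[real])
  d <- as.matrix(stats::dist(mol$xyz[real, , drop = FALSE]))
  cut <- scale * outer(r, r, `+`)
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  m <- cbind(real[hit[, 1]], real[hit[, 2]])
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  unname(m[order(m[, 1], m[, 2]), , drop = FALSE])
}

#' Perceive and attach bonds
#'
#' Convenience wrapper storing [perceive_bonds()] output on the molecule.
#' @inheritParams perceive_bonds
#' @export
with_bonds <- function(mol, scale = 1.2) {
  mol$bonds <- perceive_bonds(mol, scale)
  mol
}

#' Select an ordered editing focus
#'
#' One to four distinct atoms (dummies allowed) form the ad-hoc internal
#' coordinate under edit: 1 atom is a centre, 2 a distance, 3 a valence
#' angle (vertex in the middle), 4 a torsion A-B-C-D.  The first atom is
#' the one moved by [set_internal()].
#'
#' @param mol a molecule.
#' @param ids ordered vector of 1 to 4 distinct atom ids.
#' @return an object of class `"mol_selection"` with fields `ids` and
#'   `focus` (one of `"centre"`, `"distance"`, `"angle"`, `"torsion"`).
#' @export
select_atoms <- function(mol, ids) {
  ids <- as.integer(ids)
  if (length(ids) < 1L || length(ids) > 4L)
    stop("selection must contain 1 to 4 atoms", call. = FALSE)
  if (anyDuplicated(ids))
    stop("selection ids must be distinct", call. = FALSE)
  if (any(ids < 1L | ids > n_atoms(mol)))
    stop("selection id out of range", call. = FALSE)
  focus <- c("centre", "distance", "angle", "torsion")[length(ids)]
  structure(list(ids = ids, focus = focus), class = "mol_selection")
}

#' @export
print.mol_selection <- function(x, ...) {
  cat(sprintf("selection (%s): %s\n", x$focus, paste(x$ids, collapse = " ")))
  invisible(x)
}

#' Mark an unordered group of atoms
#'
#' Groups are the unit of "apply to many atoms at once" operations: rigid
#' internal-coordinate edits and symmetry replication.  Membership rules:
#' `explicit` (a given id set), `same_element` (all atoms of one element),
#' `bonded_to` (an anchor atom plus its bonded neighbours), and
#' `side_of_bond` (the connected component containing `side` once the
#' bond `a`-`b` is deleted from the bond graph).
#'
#' @param mol a molecule.
#' @param rule one of `"explicit"`, `"same_element"`, `"bonded_to"`,
#'   `"side_of_bond"`.
#' @param ids explicit member ids (rule `"explicit"`).
#' @param element element symbol (rule `"same_element"`).
#' @param anchor anchor atom id (rule `"bonded_to"`).
#' @param bond length-2 atom-id vector naming the bond (rule
#'   `"side_of_bond"`).
#' @param side atom id marking the side kept (rule `"side_of_bond"`);
#'   defaults to the first bond endpoint.
#' @param scale bond-perception scale used when the molecule carries no
#'   bonds.
#' @return an object of class `"mol_group"` with fields `members`
#'   (sorted ids) and `rule`.
#' @export
mark_group <- function(mol, rule = c("explicit", "same_element",
                                     "bonded_to", "side_of_bond"),
                       ids = NULL, element = NULL, anchor = NULL,
                       bond = NULL, side = NULL, scale = 1.2) {
  rule <- match.arg(rule)
  n <- n_atoms(mol)
  members <- switch(rule,
    explicit = {
      ids <- as.integer(ids)
      if (any(ids < 1L | ids > n)) stop("group id out of range", call. = FALSE)
      ids
    },
    same_element = {
      check_elements(element)
      which(mol$element == element)
    },
    bonded_to = {
      anchor <- as.integer(anchor)
      if (anchor < 1L || anchor > n) stop("anchor out of range", call. = FALSE)
      b <- if (is.null(mol$bonds)) perceive_bonds(mol, scale) else mol$bonds
      nb <- c(b[b[, 1] == anchor, 2], b[b[, 2] == anchor, 1])
      c(anchor, nb)
    },
    side_of_bond = {
      b <- if (is.null(mol$bonds)) perceive_bonds(mol, scale) else mol$bonds
      bond <- sort(as.integer(bond))
      hit <- b[, 1] == bond[1] & b[, 2] == bond[2]
      if (!any(hit)) stop("no such bond", call. = FALSE)
      if (is.null(side)) side <- bond[1]
      side <- as.integer(side)
      keep <- b[!hit, , drop = FALSE]
      comp <- components_from_edges(n, keep)
      other <- setdiff(bond, side)
      if (comp[side] == comp[other])
        stop("bond is in a cycle", call. = FALSE)
      which(comp == comp[side])
    })
  structure(list(members = sort(unique(as.integer(members))), rule = rule),
            class = "mol_group")
}

components_from_edges <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' @export
print.mol_group <- function(x, ...) {
  cat(sprintf("group (%s): %d atoms\n", x$rule, length(x$members)))
  invisible(x)
}

#' Delete atoms, compacting ids
#'
#' Remaining atoms are renumbered 1..n'; the old-to-new id map is attached
#' as attribute `"id_map"` (NA for deleted ids).  Bonds incident to deleted
#' atoms are dropped; frames and charges are subset accordingly.
#'
#' @param mol a molecule.
#' @param ids atom ids to remove.
#' @export
delete_atoms <- function(mol, ids) {
  ids <- unique(as.integer(ids))
  if (any(ids < 1L | ids > n_atoms(mol)))
    stop("delete id out of range", call. = FALSE)
  keep <- setdiff(seq_len(n_atoms(mol)), ids)
  map <- rep(NA_integer_, n_atoms(mol))
  map[keep] <- seq_along(keep)
  out <- mol
  out$element <- mol$element[keep]
  out$xyz <- mol$xyz[keep, , drop = FALSE]
  out$charge <- mol$charge[keep]
  if (!is.null(mol$bonds)) {
    b <- mol$bonds
    ok <- !(b[, 1] %in% ids | b[, 2] %in% ids)
    out$bonds <- matrix(map[b[ok, , drop = FALSE]], ncol = 2)
  }
  if (!is.null(mol$frames))
    out$frames <- lapply(mol$frames, function(f) f[keep, , drop = FALSE])
  attr(out, "id_map") <- map
  out
}

#' Append atoms
#'
#' @param mol a molecule.
#' @param element element symbols of the new atoms.
#' @param xyz coordinates (k x 3) of the new atoms.
#' @param charge optional charges for the new atoms.
#' @return the extended molecule (bonds are left as-is; re-perceive if
#'   needed).
#' @export
add_atoms <- function(mol, element, xyz, charge = NULL) {
  element <- as.character(element)
  check_elements(element)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (is.null(charge)) charge <- rep(NA_real_, length(element))
  out <- mol
  out$element <- c(mol$element, element)
  out$xyz <- rbind(mol$xyz, xyz)
  out$charge <- c(mol$charge, as.numeric(charge))
  if (!is.null(mol$frames))
    out$frames <- lapply(mol$frames, function(f) rbind(f, xyz))
  out
}

sync_frame1 <- function(mol) {
  if (!is.null(mol$frames)) mol$frames[[1]] <- mol$xyz
  mol
}
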