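# Periodic-table data used across the package.
#
# Covalent radii are the Cordero (2008) single-bond radii in angstrom; for
# Mn, Fe and Co the low-spin values are used so the table is single-valued.
# Masses are standard atomic weights.  The reserved symbol "X" denotes a
# dummy atom: massless, bondless, usable as a pivot for edits and symmetry
# operations.

.element_table <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
           "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
           "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
           "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
           "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "W", "Re", "Os",
           "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")
  z <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
         11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L,
         21L, 22L, 23L, 24L, 25L, 26L, 27L, 28L, 29L, 30L,
         31L, 32L, 33L, 34L, 35L, 36L, 37L, 38L, 39L, 40L,
         41L, 42L, 43L, 44L, 45L, 46L, 47L, 48L, 49L, 50L,
         51L, 52L, 53L, 54L, 55L, 56L, 57L, 74L, 75L, 76L,
         77L, 78L, 79L, 80L, 81L, 82L, 83L)
  rcov <- c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
            1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
            1.70, 1.60, 1.53, 1.39, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22,
            1.22, 1.20, 1.19, 1.20, 1.20, 1.16, 2.20, 1.95, 1.90, 1.75,
            1.64, 1.54, 1.47, 1.46, 1.42, 1.39, 1.45, 1.44, 1.42, 1.39,
            1.39, 1.38, 1.39, 1.40, 2.44, 2.15, 2.07, 1.62, 1.51, 1.44,
            1.41, 1.36, 1.36, 1.32, 1.45, 1.46, 1.48)
  mass <- c(1.008, 4.003, 6.94, 9.012, 10.81, 12.011, 14.007, 15.999,
            18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974,
            32.06, 35.45, 39.948, 39.098, 40.078, 44.956, 47.867,
            50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546,
            65.38, 69.723, 72.630, 74.922, 78.971, 79.904, 83.798,
            85.468, 87.62, 88.906, 91.224, 92.906, 95.95, 98.0,
            101.07, 102.906, 106.42, 107.868, 112.414, 114.818,
            118.710, 121.760, 127.60, 126.904, 131.293, 132.905,
            137.327, 138.905, 183.84, 186.207, 190.23, 192.217,
            195.084, 196.967, 200.592, 204.38, 207.2, 208.980)
  data.frame(symbol = sym, number = z, rcov = rcov, mass = mass,
             stringsAsFactors = FALSE)
})

#' Dummy-atom element token
#'
#' The reserved element symbol for dummy atoms (pivot points that never
#' participate in bonds and carry no mass).
#' @export
DUMMY <- "X"

#' Bohr radius in angstrom (CODATA)
#' @export
BOHR_ANGSTROM <- 0.529177210903

is_dummy_symbol <- function(el) el == DUMMY

check_elements <- function(el) {
  bad <- setdiff(unique(el), c(.element_table$symbol, DUMMY))
  if (length(bad) > 0L)
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(el)
}

element_property <- function(el, what) {
  check_elements(el)
  idx <- match(el, .element_table$symbol)
  out <- .element_table[[what]][idx]
  # dummies: massless, no covalent radius, no atomic number
  out[is_dummy_symbol(el)] <- if (what == "number") NA_integer_ else NA_real_
  out
}

#' Covalent radii
#'
#' Single-bond covalent radii (angstrom) for chemical symbols; `NA` for the
#' dummy token `"X"`.
#' @param el character vector of element symbols.
#' @return numeric vector of radii in angstrom.
#' @export
covalent_radius <- function(el) element_property(el, "rcov")

#' Atomic masses
#' @param el character vector of element symbols.
#' @return numeric vector of standard atomic weights; `NA` for dummies.
#' @export
atomic_mass <- function(el) element_property(el, "mass")

#' Atomic numbers
#' @param el character vector of element symbols.
#' @return integer vector; `NA` for dummies.
#' @export
atomic_number <- function(el) element_property(el, "number")

symbol_from_number <- function(z) {
  idx <- match(z, .element_table$number)
  if (anyNA(idx))
    stop("unknown atomic number(s): ",
         paste(unique(z[is.na(idx)]), collapse = ", "), call. = FALSE)
  .element_table$symbol[idx]
}
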