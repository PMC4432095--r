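# Gaussian-cube volumetric I/O.  Cube files carry lattice metadata in
# bohr and values in z-fastest order; both are converted at this boundary
# (internal storage is angstrom, first-axis-fastest R arrays).

#' Read a Gaussian cube file
#'
#' @param path file path.
#' @return a [scalar_grid()]; the atom block, if present, is attached as
#'   field `molecule`.
#' @export
read_grid_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("truncated cube file", call. = FALSE)
  label <- trimws(lines[1])
  hdr <- strsplit(trimws(lines[3]), "[[:space:]]+")
  hdr <- suppressWarnings(as.numeric(hdr[[1]]))
  natoms <- as.integer(hdr[1])
  if (is.na(natoms))
    stop("cube header: unparseable atom count", call. = FALSE)
  origin <- hdr[2:4] * BOHR_ANGSTROM
  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (d in 1:3) {
    ax <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[3L + d]), "[[:space:]]+")[[1]]))
    shape[d] <- as.integer(ax[1])
    axes[d, ] <- ax[2:4] * BOHR_ANGSTROM
  }
  if (any(is.na(shape)) || any(shape < 1L))
    stop("cube header: bad voxel counts", call. = FALSE)
  mol <- NULL
  if (natoms > 0L) {
    at <- matrix(0, natoms, 5)
    for (k in seq_len(natoms)) {
      at[k, ] <- suppressWarnings(as.numeric(
        strsplit(trimws(lines[6L + k]), "[[:space:]]+")[[1]][1:5]))
    }
    mol <- molecule(symbol_from_number(as.integer(at[, 1])),
                    at[, 3:5] * BOHR_ANGSTROM,
                    charge = at[, 2])
  }
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(7L + natoms):length(lines)]), "[[:space:]]+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape))
    stop(sprintf("cube: %d values but header promises %d",
                 length(vals), prod(shape)), call. = FALSE)
  # cube order is z-fastest (x outer, y, z inner); R arrays are x-fastest
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  g <- scalar_grid(origin, axes, arr, label = label)
  g$molecule <- mol
  g
}

#' Write a Gaussian cube file
#'
#' Lengths are converted to bohr; values are written z-fastest, six per
#' line, with enough digits to round-trip to 1e-10.
#'
#' @param grid a [scalar_grid()].
#' @param path output path.
#' @param mol optional molecule for the atom block (defaults to
#'   `grid$molecule`); dummy atoms are skipped.
#' @export
write_grid_cube <- function(grid, path, mol = grid$molecule) {
  b <- 1 / BOHR_ANGSTROM
  lines <- c(if (nzchar(grid$label)) grid$label else "scalar field",
             "written by molforge")
  atoms <- if (!is.null(mol)) which(!is_dummy_symbol(mol$element)) else integer(0)
  lines <- c(lines, sprintf("%5d %12.6f %12.6f %12.6f", length(atoms),
                            grid$origin[1] * b, grid$origin[2] * b,
                            grid$origin[3] * b))
  for (d in 1:3)
    lines <- c(lines, sprintf("%5d %12.6f %12.6f %12.6f", grid$shape[d],
                              grid$axes[d, 1] * b, grid$axes[d, 2] * b,
                              grid$axes[d, 3] * b))
  for (k in atoms) {
    q <- if (is.na(mol$charge[k])) 0 else mol$charge[k]
    lines <- c(lines, sprintf("%5d %12.6f %12.6f %12.6f %12.6f",
                              atomic_number(mol$element[k]), q,
                              mol$xyz[k, 1] * b, mol$xyz[k, 2] * b,
                              mol$xyz[k, 3] * b))
  }
  vals <- as.numeric(aperm(grid$values, c(3, 2, 1)))  # z-fastest
  rows <- split(vals, (seq_along(vals) - 1L) %/% 6L)
  lines <- c(lines, vapply(rows, function(r)
    paste(sprintf("% .10E", r), collapse = " "), ""))
  writeLines(lines, path)
  invisible(path)
}
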