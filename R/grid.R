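# Volumetric scalar fields on (possibly non-orthogonal) lattices.
#
# Values are stored as an R array with dim = shape, so the first lattice
# axis is the fastest-varying index in memory (column-major, the native R
# layout).  File formats with other orderings (Gaussian cube is
# z-fastest) convert at the I/O boundary.  All lattice metadata is in
# angstrom internally.

#' Construct a scalar grid
#'
#' @param origin length-3 numeric, angstrom.
#' @param axes 3 x 3 numeric matrix; row i is the voxel step along lattice
#'   axis i (angstrom).  Axes must be linearly independent but need not be
#'   orthogonal.
#' @param values numeric array with `dim = shape`, or a vector of length
#'   `prod(shape)` (filled first-axis fastest).
#' @param shape integer length-3; inferred from `values` when it is an
#'   array.
#' @param label free-text label.
#' @return an object of class `"scalar_grid"`.
#' @export
scalar_grid <- function(origin, axes, values, shape = NULL, label = "") {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  if (abs(det(axes)) < 1e-12)
    stop("grid axes are linearly dependent", call. = FALSE)
  if (is.null(shape)) {
    if (is.null(dim(values)) || length(dim(values)) != 3L)
      stop("shape required when values is not a 3-d array", call. = FALSE)
    shape <- dim(values)
  }
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("shape must be positive", call. = FALSE)
  if (length(values) != prod(shape))
    stop("value count does not match shape", call. = FALSE)
  structure(list(origin = origin, axes = unname(axes),
                 values = array(as.numeric(values), dim = shape),
                 shape = shape, label = label),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("scalar grid %dx%dx%d%s, values in [%g, %g]\n",
              x$shape[1], x$shape[2], x$shape[3],
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              min(x$values), max(x$values)))
  invisible(x)
}

same_lattice <- function(a, b, tol = 1e-9) {
  if (!identical(a$shape, b$shape)) return("shape")
  if (max(abs(a$origin - b$origin)) > tol) return("origin")
  if (max(abs(a$axes - b$axes)) > tol) return("axes")
  NULL
}

#' Cartesian coordinates of all lattice points
#'
#' @param grid a scalar grid.
#' @return `prod(shape)` x 3 matrix in the storage order of `values`.
#' @export
grid_coordinates <- function(grid) {
  ix <- seq_len(grid$shape[1]) - 1
  iy <- seq_len(grid$shape[2]) - 1
  iz <- seq_len(grid$shape[3]) - 1
  idx <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
  sweep(idx %*% grid$axes, 2, grid$origin, `+`)
}

#' Volume integral of a grid (midpoint quadrature)
#'
#' @param grid a scalar grid.
#' @return `sum(values) * voxel_volume`.
#' @export
grid_integral <- function(grid) {
  sum(grid$values) * abs(det(grid$axes))
}

#' Linear combination of grids
#'
#' `sum_k coefficients[k] * grids[[k]]`, pointwise; all grids must share
#' origin, axes and shape to within 1e-9.  Useful for spin densities
#' (alpha minus beta) and difference densities.
#'
#' @param grids list of scalar grids on one lattice.
#' @param coefficients numeric vector, one per grid.
#' @return a scalar grid; the label concatenates the input labels.
#' @export
combine_grids <- function(grids, coefficients) {
  stopifnot(length(grids) >= 1L, length(coefficients) == length(grids))
  g0 <- grids[[1]]
  for (k in seq_along(grids)[-1]) {
    bad <- same_lattice(g0, grids[[k]])
    if (!is.null(bad))
      stop(sprintf("grid %d lattice mismatch in field '%s'", k, bad),
           call. = FALSE)
  }
  vals <- array(0, dim = g0$shape)
  for (k in seq_along(grids))
    vals <- vals + coefficients[k] * grids[[k]]$values
  lab <- paste(vapply(seq_along(grids), function(k)
    sprintf("%+g*%s", coefficients[k],
            if (nzchar(grids[[k]]$label)) grids[[k]]$label else
              sprintf("grid%d", k)), ""), collapse = " ")
  scalar_grid(g0$origin, g0$axes, vals, label = lab)
}

#' Electron density from occupied orbitals
#'
#' `rho = sum_i n_i * psi_i^2` pointwise over a shared lattice.
#'
#' @param grids list of orbital amplitude grids.
#' @param occupations numeric vector of occupation numbers (>= 0).
#' @return the density grid.
#' @export
density_from_orbitals <- function(grids, occupations) {
  stopifnot(length(grids) == length(occupations))
  if (any(occupations < 0)) stop("occupations must be >= 0", call. = FALSE)
  g0 <- grids[[1]]
  for (k in seq_along(grids)[-1]) {
    bad <- same_lattice(g0, grids[[k]])
    if (!is.null(bad))
      stop(sprintf("grid %d lattice mismatch in field '%s'", k, bad),
           call. = FALSE)
  }
  vals <- array(0, dim = g0$shape)
  for (k in seq_along(grids))
    vals <- vals + occupations[k] * grids[[k]]$values^2
  scalar_grid(g0$origin, g0$axes, vals, label = "density")
}

#' Trilinear interpolation of a grid at arbitrary points
#'
#' Points outside the lattice are clamped to the boundary; the ids of
#' clamped points are attached as attribute `"clamped"`.
#'
#' @param grid a scalar grid.
#' @param points m x 3 matrix of Cartesian positions (angstrom).
#' @return numeric vector of interpolated values.
#' @export
grid_interpolate <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  # fractional lattice coordinates: p = origin + f %*% axes
  f <- sweep(points, 2, grid$origin, `-`) %*% solve(grid$axes)
  hi <- grid$shape - 1L
  clamped <- which(apply(f < -1e-9, 1, any) |
                   apply(sweep(f, 2, hi + 1e-9, `>`), 1, any))
  for (d in 1:3) f[, d] <- pmin(pmax(f[, d], 0), hi[d])
  i0 <- pmin(floor(f), matrix(rep(hi - 1L, each = nrow(f)), ncol = 3))
  i0 <- matrix(as.integer(pmax(i0, 0)), ncol = 3)
  w <- f - i0
  v <- grid$values
  n1 <- grid$shape[1]; n12 <- grid$shape[1] * grid$shape[2]
  at <- function(dx, dy, dz)
    v[1L + (i0[, 1] + dx) + (i0[, 2] + dy) * n1 + (i0[, 3] + dz) * n12]
  out <-
    at(0L, 0L, 0L) * (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) +
    at(1L, 0L, 0L) * w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) +
    at(0L, 1L, 0L) * (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) +
    at(1L, 1L, 0L) * w[, 1] * w[, 2] * (1 - w[, 3]) +
    at(0L, 0L, 1L) * (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] +
    at(1L, 0L, 1L) * w[, 1] * (1 - w[, 2]) * w[, 3] +
    at(0L, 1L, 1L) * (1 - w[, 1]) * w[, 2] * w[, 3] +
    at(1L, 1L, 1L) * w[, 1] * w[, 2] * w[, 3]
  attr(out, "clamped") <- clamped
  out
}
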