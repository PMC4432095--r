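# Triangulated isosurfaces of scalar grids.

#' Construct a mesh
#'
#' @param vertices n x 3 numeric matrix, angstrom.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param vertex_scalar optional per-vertex scalar values.
#' @param rgba base colour (length-4, components in `[0, 1]`).
#' @param opacity opacity in `[0, 1]`.
#' @return an object of class `"mesh"`.
#' @export
mesh <- function(vertices, triangles, vertex_scalar = NULL,
                 rgba = c(0.7, 0.7, 0.9, 1), opacity = 1) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle index out of range", call. = FALSE)
  if (!is.null(vertex_scalar) && length(vertex_scalar) != nrow(vertices))
    stop("one scalar per vertex required", call. = FALSE)
  if (opacity < 0 || opacity > 1)
    stop("opacity must lie in [0, 1]", call. = FALSE)
  structure(list(vertices = vertices, triangles = triangles,
                 vertex_scalar = vertex_scalar,
                 style = list(rgba = as.numeric(rgba),
                              opacity = as.numeric(opacity))),
            class = "mesh")
}

#' @export
print.mesh <- function(x, ...) {
  cat(sprintf("mesh: %d vertices, %d triangles%s\n", nrow(x$vertices),
              nrow(x$triangles),
              if (!is.null(x$vertex_scalar)) ", with vertex scalars" else ""))
  invisible(x)
}

#' Extract an isosurface
#'
#' Marching-tetrahedra triangulation of the level set `values == isovalue`
#' with linear interpolation along lattice edges.  An isovalue outside the
#' grid's value range yields an empty mesh.
#'
#' @param grid a [scalar_grid()].
#' @param isovalue finite contour level.
#' @return a [mesh()].
#' @export
isosurface <- function(grid, isovalue) {
  if (!is.finite(isovalue)) stop("isovalue must be finite", call. = FALSE)
  if (any(grid$shape < 2L))
    stop("grid must have at least 2 points per axis", call. = FALSE)
  res <- .mtetra(as.numeric(grid$values), grid$shape, grid$origin,
                 grid$axes, isovalue)
  mesh(res$vertices, res$triangles)
}

#' Signed orbital isosurfaces
#'
#' Orbital amplitudes carry sign; the conventional display is a pair of
#' surfaces, one at `+|isovalue|` and one at `-|isovalue|`.
#'
#' @param grid a [scalar_grid()] of signed amplitudes.
#' @param isovalue contour magnitude.
#' @return list with components `positive` and `negative`, both meshes.
#' @export
signed_isosurfaces <- function(grid, isovalue) {
  v <- abs(isovalue)
  list(positive = isosurface(grid, v), negative = isosurface(grid, -v))
}

#' Colour a mesh by a scalar field
#'
#' Vertex scalars are the field evaluated at every vertex: trilinear
#' interpolation for grids, Coulomb point-charge summation for ESP
#' sources.  Vertices outside a grid's bounding box are clamped and
#' reported via attribute `"clamped"`.
#'
#' @param m a [mesh()].
#' @param field a [scalar_grid()], or a list with `positions` (k x 3,
#'   angstrom) and `charges` (length k) for point-charge ESP.
#' @param ... passed on to [esp_point_charges()] (e.g. `chunk`).
#' @return the mesh with `vertex_scalar` set.
#' @export
color_mesh_by_field <- function(m, field, ...) {
  if (inherits(field, "scalar_grid")) {
    s <- grid_interpolate(field, m$vertices)
    m$vertex_scalar <- as.numeric(s)
    attr(m, "clamped") <- attr(s, "clamped")
  } else if (is.list(field) && !is.null(field$positions)) {
    m$vertex_scalar <- esp_point_charges(m$vertices, field$positions,
                                         field$charges, ...)
  } else stop("field must be a scalar_grid or a point-charge list",
              call. = FALSE)
  m
}

#' Euler characteristic of a mesh
#'
#' `V - E + F` with edges counted once; 2 for a closed surface of genus 0.
#'
#' @param m a [mesh()].
#' @export
euler_characteristic <- function(m) {
  tr <- m$triangles
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  nrow(m$vertices) - nrow(ed) + nrow(tr)
}
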