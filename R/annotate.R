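# Geometric annotation objects (arrows, spheres, planes, triangles,
# parallelepipeds) and headless scene export to ascii PLY with per-vertex
# colours.

OBJECT_KINDS <- c(arrow = 2L, sphere = 1L, plane = 3L, triangle = 3L,
                  parallelepiped = 4L)

#' Construct a geometric annotation object
#'
#' Defining points may come from atoms or dummy pivot points.  Point
#' counts by kind: arrow 2 (tail, head), sphere 1 (centre; radius in
#' `magnitude`), plane 3, triangle 3, parallelepiped 4 (origin plus three
#' edge endpoints).
#'
#' @param kind one of `"arrow"`, `"sphere"`, `"plane"`, `"triangle"`,
#'   `"parallelepiped"`.
#' @param points k x 3 matrix of defining points, angstrom.
#' @param rgba colour, components in `[0, 1]`.
#' @param opacity opacity in `[0, 1]`; annotation objects default to
#'   translucent (0.5) since many enclose atoms.
#' @param magnitude optional scalar (sphere radius; arrow length scale).
#' @return an object of class `"geom_object"`.
#' @export
geom_object <- function(kind, points, rgba = c(0.5, 0.5, 0.8, 1),
                        opacity = 0.5, magnitude = NULL) {
  if (!kind %in% names(OBJECT_KINDS))
    stop("unknown object kind: ", kind, call. = FALSE)
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) != OBJECT_KINDS[[kind]])
    stop(sprintf("%s requires %d point(s), got %d", kind,
                 OBJECT_KINDS[[kind]], nrow(points)), call. = FALSE)
  if (opacity < 0 || opacity > 1)
    stop("opacity must lie in [0, 1]", call. = FALSE)
  if (kind %in% c("plane", "triangle")) {
    n <- crossv(points[2, ] - points[1, ], points[3, ] - points[1, ])
    if (vnorm(n) < 1e-9)
      stop("degenerate ", kind, ": collinear points", call. = FALSE)
  }
  if (kind == "sphere" && (is.null(magnitude) || magnitude <= 0))
    stop("sphere requires a positive radius in 'magnitude'", call. = FALSE)
  structure(list(kind = kind, points = unname(points),
                 rgba = as.numeric(rgba), opacity = as.numeric(opacity),
                 magnitude = magnitude),
            class = "geom_object")
}

#' Add an annotation object to a document
#'
#' @param doc an [mfx_doc()].
#' @param kind object kind (see [geom_object()]).
#' @param selection selection or atom-id vector supplying the defining
#'   points (dummy atoms allowed), or `NULL` when `points` is given.
#' @param points explicit k x 3 matrix of defining points.
#' @param ... style arguments passed to [geom_object()].
#' @return the document with the object appended.
#' @export
add_object <- function(doc, kind, selection = NULL, points = NULL, ...) {
  if (is.null(points)) {
    ids <- if (inherits(selection, "mol_selection")) selection$ids
           else as.integer(selection)
    points <- doc$molecule$xyz[ids, , drop = FALSE]
  }
  doc$objects[[length(doc$objects) + 1L]] <-
    geom_object(kind, points, ...)
  doc
}

#' Add dipole-moment arrows
#'
#' For a document whose metadata carries a `dipole` vector (debye), adds
#' one arrow from the charge-weighted centroid (geometric centroid when
#' no charges are assigned) along the dipole, with length `|mu| * scale`.
#' Documents carrying per-molecule dipoles (`molecule_dipoles`, one row
#' per sub-molecule, plus `molecule_index` per atom) get one arrow per
#' sub-molecule.  A zero dipole adds nothing.
#'
#' @param doc an [mfx_doc()].
#' @param scale arrow length per debye (angstrom/debye, default 0.4).
#' @return the document with arrows appended.
#' @export
dipole_arrow <- function(doc, scale = 0.4) {
  mol <- doc$molecule
  md <- mol$metadata
  anchor_of <- function(ids) {
    w <- abs(mol$charge[ids])
    if (all(is.na(w)) || sum(w, na.rm = TRUE) == 0)
      colMeans(mol$xyz[ids, , drop = FALSE])
    else {
      w[is.na(w)] <- 0
      colSums(mol$xyz[ids, , drop = FALSE] * w) / sum(w)
    }
  }
  add_arrow <- function(doc, anchor, mu) {
    len <- vnorm(mu)
    if (len < 1e-12) return(doc)
    add_object(doc, "arrow",
               points = rbind(anchor, anchor + scale * mu),
               rgba = c(0.9, 0.6, 0.1, 1), opacity = 1, magnitude = len)
  }
  if (!is.null(md$molecule_dipoles)) {
    mu <- matrix(md$molecule_dipoles, ncol = 3)
    idx <- md$molecule_index
    for (k in seq_len(nrow(mu)))
      doc <- add_arrow(doc, anchor_of(which(idx == k)), mu[k, ])
  } else if (!is.null(md$dipole)) {
    doc <- add_arrow(doc, anchor_of(seq_len(n_atoms(mol))), md$dipole)
  }
  doc
}

#' Triangulate an annotation object
#'
#' @param obj a [geom_object()].
#' @param segments circle resolution for arrows and spheres.
#' @return a [mesh()] carrying the object's style.
#' @export
object_mesh <- function(obj, segments = 16L) {
  p <- obj$points
  vt <- switch(obj$kind,
    triangle = list(v = p, t = matrix(c(1L, 2L, 3L), 1)),
    plane = {
      # parallelogram spanned at p1 by the two edge vectors
      v <- rbind(p[1, ], p[2, ], p[2, ] + p[3, ] - p[1, ], p[3, ])
      list(v = v, t = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
    },
    parallelepiped = {
      a <- p[2, ] - p[1, ]; b <- p[3, ] - p[1, ]; cc <- p[4, ] - p[1, ]
      corners <- t(vapply(0:7, function(k)
        p[1, ] + bitwAnd(k, 1L) * a + (bitwAnd(k, 2L) / 2) * b +
          (bitwAnd(k, 4L) / 4) * cc, numeric(3)))
      faces <- rbind(c(1, 2, 4, 3), c(5, 6, 8, 7), c(1, 2, 6, 5),
                     c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 4, 8, 6))
      t <- do.call(rbind, lapply(seq_len(nrow(faces)), function(i)
        rbind(faces[i, c(1, 2, 3)], faces[i, c(1, 3, 4)])))
      list(v = corners, t = t)
    },
    sphere = uv_sphere(p[1, ], obj$magnitude, segments),
    arrow = arrow_mesh(p[1, ], p[2, ], segments))
  mesh(vt$v, vt$t, rgba = obj$rgba, opacity = obj$opacity)
}

uv_sphere <- function(centre, r, seg) {
  nth <- max(4L, seg %/% 2L); nph <- max(6L, seg)
  th <- seq(0, pi, length.out = nth + 1L)
  ph <- seq(0, 2 * pi, length.out = nph + 1L)[-(nph + 1L)]
  v <- list(centre + c(0, 0, r))
  for (i in seq(2, nth)) for (j in seq_len(nph))
    v[[length(v) + 1L]] <- centre + r * c(sin(th[i]) * cos(ph[j]),
                                          sin(th[i]) * sin(ph[j]),
                                          cos(th[i]))
  v[[length(v) + 1L]] <- centre - c(0, 0, r)
  V <- do.call(rbind, v)
  idx <- function(i, j) 1L + (i - 2L) * nph + ((j - 1L) %% nph) + 1L
  tr <- list()
  for (j in seq_len(nph)) {
    tr[[length(tr) + 1L]] <- c(1L, idx(2L, j), idx(2L, j + 1L))
    tr[[length(tr) + 1L]] <- c(nrow(V), idx(nth, j + 1L), idx(nth, j))
  }
  if (nth > 2L) for (i in seq(2L, nth - 1L)) for (j in seq_len(nph)) {
    tr[[length(tr) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    tr[[length(tr) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  list(v = V, t = do.call(rbind, tr))
}

arrow_mesh <- function(tail, head, seg) {
  axis <- head - tail
  len <- vnorm(axis)
  u <- unitv(axis)
  perp <- unitv(crossv(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  perp2 <- crossv(u, perp)
  rs <- 0.03 * len; rh <- 0.08 * len
  base <- tail + 0.75 * axis
  ph <- seq(0, 2 * pi, length.out = seg + 1L)[-(seg + 1L)]
  ring <- function(c0, r) t(vapply(ph, function(a)
    c0 + r * (cos(a) * perp + sin(a) * perp2), numeric(3)))
  V <- rbind(tail, ring(tail, rs), ring(base, rs), ring(base, rh), head)
  nt <- nrow(V)
  i1 <- 2L:(seg + 1L); i2 <- (seg + 2L):(2L * seg + 1L)
  i3 <- (2L * seg + 2L):(3L * seg + 1L)
  nxt <- function(i, set) set[(match(i, set) %% seg) + 1L]
  tr <- list()
  for (k in seq_len(seg)) {
    a <- i1[k]; b <- nxt(a, i1); cc <- i2[k]; d <- nxt(cc, i2)
    e <- i3[k]; f <- nxt(e, i3)
    tr[[length(tr) + 1L]] <- c(1L, b, a)              # tail cap
    tr[[length(tr) + 1L]] <- c(a, b, d); tr[[length(tr) + 1L]] <- c(a, d, cc)
    tr[[length(tr) + 1L]] <- c(cc, d, f); tr[[length(tr) + 1L]] <- c(cc, f, e)
    tr[[length(tr) + 1L]] <- c(e, f, nt)              # cone
  }
  list(v = V, t = do.call(rbind, tr))
}

#' Diverging colour map symmetric about zero
#'
#' Blue-white-red with limits `±max|scalar|`.
#'
#' @param scalar numeric vector.
#' @return n x 3 matrix of RGB values in `[0, 1]`.
#' @export
diverging_colors <- function(scalar) {
  lim <- max(abs(scalar), 1e-300)
  t <- (scalar / lim + 1) / 2
  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  ramp(pmin(pmax(t, 0), 1)) / 255
}

#' Export meshes to ascii PLY
#'
#' Vertices carry RGBA colours: from the diverging map over
#' `vertex_scalar` when present (symmetric about zero), else the mesh's
#' base colour.  One file per mesh; with several meshes a numbered suffix
#' is inserted before the extension.
#'
#' @param meshes a [mesh()] or list of meshes.
#' @param path output path (`.ply`).
#' @return the paths written, invisibly.
#' @export
export_scene <- function(meshes, path) {
  if (inherits(meshes, "mesh")) meshes <- list(meshes)
  paths <- if (length(meshes) == 1L) path else
    vapply(seq_along(meshes), function(k)
      sub("(\\.[^.]*)?$", sprintf("_%d\\1", k), path), "")
  for (k in seq_along(meshes)) write_ply(meshes[[k]], paths[k])
  invisible(paths)
}

write_ply <- function(m, path) {
  nv <- nrow(m$vertices); nf <- nrow(m$triangles)
  col <- if (!is.null(m$vertex_scalar))
    diverging_colors(m$vertex_scalar)
  else matrix(rep(m$style$rgba[1:3], each = nv), nv)
  alpha <- round(255 * m$style$opacity)
  rgb255 <- round(255 * col)
  hdr <- c("ply", "format ascii 1.0",
           "comment written by molforge",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green",
           "property uchar blue", "property uchar alpha",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.6f %.6f %.6f %d %d %d %d",
                m$vertices[, 1], m$vertices[, 2], m$vertices[, 3],
                rgb255[, 1], rgb255[, 2], rgb255[, 3],
                rep(alpha, nv))
  fl <- sprintf("3 %d %d %d", m$triangles[, 1] - 1L,
                m$triangles[, 2] - 1L, m$triangles[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read an ascii PLY file
#'
#' Minimal reader for the files written by [export_scene()] (and other
#' ascii PLY with leading x/y/z properties).
#'
#' @param path file path.
#' @return a [mesh()]; vertex colours, if present, are attached as
#'   attribute `"rgb"`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply") stop("not a PLY file", call. = FALSE)
  endh <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1]))
  vdat <- do.call(rbind, lapply(lines[endh + seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  fdat <- do.call(rbind, lapply(lines[endh + nv + seq_len(nf)], function(l)
    as.integer(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  m <- mesh(vdat[, 1:3, drop = FALSE],
            fdat[, 2:4, drop = FALSE] + 1L)
  if (ncol(vdat) >= 6) attr(m, "rgb") <- vdat[, 4:6, drop = FALSE] / 255
  m
}
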