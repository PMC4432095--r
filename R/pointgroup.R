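# Point-group detection.
#
# The molecule is centred on its mass-weighted centroid; candidate axes
# come from the inertia eigenvectors, centre->atom vectors, midpoints of
# same-element atom pairs and cross products of centre->atom pairs.
# Proper rotations (orders 2-8), mirror planes, inversion and improper
# axes are accepted when they map the atom set onto itself, element by
# element, within `tol`.  The Schoenflies symbol is assembled by the
# conventional decision tree (linear -> Cinfv/Dinfh; several high-order
# axes -> cubic/icosahedral families; otherwise the principal-axis tree).
# Translations are building tools only and are never considered here.

#' Detect the point group of a molecule
#'
#' @param mol a molecule (dummy atoms are ignored).
#' @param tol matching tolerance in angstrom (default 0.1).
#' @param max_order highest rotation order searched (default 8).
#' @return an object of class `"point_group"`: a list with `schoenflies`
#'   (the symbol), `elements` (data frame of accepted symmetry elements
#'   with kind, order and axis/normal direction), and `tol`.
#' @export
detect_point_group <- function(mol, tol = 0.1, max_order = 8L) {
  stopifnot(tol > 0)
  real <- which(!is_dummy_symbol(mol$element))
  if (length(real) == 0L) stop("no non-dummy atoms", call. = FALSE)
  el <- mol$element[real]
  m <- atomic_mass(el)
  X <- mol$xyz[real, , drop = FALSE]
  ctr <- colSums(X * m) / sum(m)
  X <- sweep(X, 2, ctr, `-`)
  n <- nrow(X)
  if (n == 1L || max(sqrt(rowSums(X^2))) < tol)
    return(point_group_result("Kh", data.frame(), tol))

  ok <- function(Q) maps_onto_itself(X, el, Q, tol)

  # linear?
  span <- svd(X)$d
  if (span[2] < tol) {
    lab <- if (ok(-diag(3))) "Dinfh" else "Cinfv"
    elements <- data.frame(kind = "linear_axis", order = Inf,
                           x = NA, y = NA, z = NA)
    return(point_group_result(lab, elements, tol))
  }

  axes <- candidate_axes(X, el)

  # proper rotation axes: per axis, the set of passing orders
  rot <- list()
  for (a in seq_len(nrow(axes))) {
    u <- axes[a, ]
    orders <- integer(0)
    for (k in seq(max_order, 2L)) {
      if (ok(rotation_matrix(u, 360 / k))) orders <- c(orders, k)
    }
    if (length(orders) > 0L)
      rot[[length(rot) + 1L]] <- list(axis = u, order = max(orders),
                                      orders = orders)
  }
  has_i <- ok(-diag(3))
  mirrors <- axes[vapply(seq_len(nrow(axes)), function(a)
    ok(reflection_matrix(axes[a, ])), FALSE), , drop = FALSE]

  elements <- element_table(rot, mirrors, has_i)

  rot_orders <- vapply(rot, `[[`, 0L, "order")
  high <- sum(rot_orders >= 3)

  lab <- if (high >= 2) {
    # cubic / icosahedral families
    if (any(rot_orders >= 5)) { if (has_i) "Ih" else "I" }
    else if (any(rot_orders >= 4)) { if (has_i) "Oh" else "O" }
    else if (has_i) "Th"
    else if (nrow(mirrors) > 0) "Td" else "T"
  } else if (length(rot) > 0L && max(rot_orders) >= 2) {
    principal_tree(rot, mirrors, has_i, X, el, tol, ok)
  } else {
    if (nrow(mirrors) > 0) "Cs" else if (has_i) "Ci" else "C1"
  }
  point_group_result(lab, elements, tol)
}

principal_tree <- function(rot, mirrors, has_i, X, el, tol, ok) {
  rot_orders <- vapply(rot, `[[`, 0L, "order")
  nmax <- max(rot_orders)
  p <- rot[[which.max(rot_orders)]]$axis
  # distinct C2 axes perpendicular to the principal axis
  c2perp <- 0L
  for (r in rot) {
    if (2L %in% r$orders && abs(sum(r$axis * p)) < 1e-3) c2perp <- c2perp + 1L
  }
  sigma_h <- FALSE
  n_sigma_v <- 0L
  if (nrow(mirrors) > 0) {
    dots <- abs(mirrors %*% p)
    sigma_h <- any(dots > 1 - 1e-3)
    n_sigma_v <- sum(dots < 1e-3)
  }
  if (c2perp >= nmax) {
    if (sigma_h) return(sprintf("D%dh", nmax))
    if (n_sigma_v >= nmax) return(sprintf("D%dd", nmax))
    return(sprintf("D%d", nmax))
  }
  if (sigma_h) return(sprintf("C%dh", nmax))
  if (n_sigma_v >= nmax) return(sprintf("C%dv", nmax))
  S <- reflection_matrix(p) %*% rotation_matrix(p, 360 / (2 * nmax))
  if (ok(S)) return(sprintf("S%d", 2 * nmax))
  sprintf("C%d", nmax)
}

reflection_matrix <- function(nrm) {
  nrm <- unitv(nrm)
  diag(3) - 2 * (nrm %o% nrm)
}

maps_onto_itself <- function(X, el, Q, tol) {
  Y <- X %*% t(Q)
  used <- rep(FALSE, nrow(X))
  for (i in seq_len(nrow(X))) {
    d2 <- rowSums(sweep(X, 2, Y[i, ], `-`)^2)
    d2[el != el[i] | used] <- Inf
    j <- which.min(d2)
    if (d2[j] > tol^2) return(FALSE)
    used[j] <- TRUE
  }
  TRUE
}

candidate_axes <- function(X, el) {
  cand <- list()
  # inertia principal axes
  m <- atomic_mass(el)
  r2 <- rowSums(X^2)
  I3 <- diag(c(sum(m * r2), sum(m * r2), sum(m * r2))) -
    t(X * m) %*% X
  cand[[1]] <- t(eigen(I3, symmetric = TRUE)$vectors)
  # centre -> atom
  len <- sqrt(rowSums(X^2))
  keep <- len > 1e-6
  cand[[2]] <- X[keep, , drop = FALSE] / len[keep]
  # midpoints of same-element pairs
  n <- nrow(X)
  if (n >= 2) {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pr <- pr[el[pr[, 1]] == el[pr[, 2]], , drop = FALSE]
    if (nrow(pr) > 0) {
      mid <- (X[pr[, 1], , drop = FALSE] + X[pr[, 2], , drop = FALSE]) / 2
      ml <- sqrt(rowSums(mid^2))
      k <- ml > 1e-6
      cand[[3]] <- mid[k, , drop = FALSE] / ml[k]
      # pair difference vectors (normals of planes bisecting pairs)
      dif <- X[pr[, 1], , drop = FALSE] - X[pr[, 2], , drop = FALSE]
      dl <- sqrt(rowSums(dif^2))
      k <- dl > 1e-6
      cand[[4]] <- dif[k, , drop = FALSE] / dl[k]
    }
  }
  # cross products of centre->atom pairs (limit for big molecules)
  V <- X[keep, , drop = FALSE]
  if (nrow(V) > 30) V <- V[seq_len(30), , drop = FALSE]
  if (nrow(V) >= 2) {
    cp <- list()
    for (i in seq_len(nrow(V) - 1))
      for (j in seq((i + 1), nrow(V))) {
        v <- crossv(V[i, ], V[j, ])
        if (vnorm(v) > 1e-6) cp[[length(cp) + 1]] <- v / vnorm(v)
      }
    if (length(cp) > 0) cand[[5]] <- do.call(rbind, cp)
  }
  A <- do.call(rbind, cand)
  dedupe_axes(A)
}

dedupe_axes <- function(A, tol = 1e-4) {
  # canonical sign: first component with |.| > tol positive
  for (i in seq_len(nrow(A))) {
    v <- A[i, ]
    k <- which(abs(v) > 1e-8)[1]
    if (v[k] < 0) A[i, ] <- -v
  }
  keep <- rep(TRUE, nrow(A))
  for (i in seq_len(nrow(A))) {
    if (!keep[i]) next
    if (i < nrow(A)) {
      later <- (i + 1):nrow(A)
      dots <- abs(A[later, , drop = FALSE] %*% A[i, ])
      keep[later][dots > 1 - tol] <- FALSE
    }
  }
  A[keep, , drop = FALSE]
}

element_table <- function(rot, mirrors, has_i) {
  rows <- list()
  for (r in rot)
    rows[[length(rows) + 1]] <-
      data.frame(kind = "rotation", order = r$order,
                 x = r$axis[1], y = r$axis[2], z = r$axis[3])
  if (nrow(mirrors) > 0)
    for (i in seq_len(nrow(mirrors)))
      rows[[length(rows) + 1]] <-
        data.frame(kind = "reflection", order = 2L,
                   x = mirrors[i, 1], y = mirrors[i, 2], z = mirrors[i, 3])
  if (has_i)
    rows[[length(rows) + 1]] <-
      data.frame(kind = "inversion", order = 2L, x = NA, y = NA, z = NA)
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}

point_group_result <- function(label, elements, tol) {
  structure(list(schoenflies = label, elements = elements, tol = tol),
            class = "point_group")
}

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("point group: %s (%d elements listed, tol %g A)\n",
              x$schoenflies,
              if (is.data.frame(x$elements)) nrow(x$elements) else 0L,
              x$tol))
  invisible(x)
}

#' Rotation order about a given axis
#'
#' Looks up the detected proper-rotation axis parallel to `axis` and
#' returns the corresponding rotation angle 360/order in degrees, or `NA`
#' when no such axis was found.
#'
#' @param pg a [detect_point_group()] result.
#' @param axis length-3 direction vector.
#' @return rotation angle in degrees (e.g. 180 for a two-fold axis).
#' @export
rotation_angle_about <- function(pg, axis) {
  e <- pg$elements
  if (!is.data.frame(e) || nrow(e) == 0) return(NA_real_)
  e <- e[e$kind == "rotation", , drop = FALSE]
  if (nrow(e) == 0) return(NA_real_)
  u <- unitv(as.numeric(axis))
  dots <- abs(as.matrix(e[, c("x", "y", "z")]) %*% u)
  hit <- which(dots > 1 - 1e-3)
  if (length(hit) == 0) return(NA_real_)
  360 / max(e$order[hit])
}
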