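# Symmetry operations as building tools, plus point-group detection.
#
# A sym_op is the affine isometry x -> Q x + t with Q orthogonal
# (det +1 proper, det -1 improper) assembled from selected pivot points
# (atoms or dummy atoms):
#   1 pivot  -> inversion through the point
#   2 pivots -> proper rotation about their axis, or translation by the
#               (integer multiple of the) difference vector
#   3 pivots -> reflection through their plane

#' Build a symmetry operation from pivots
#'
#' @param mol a molecule (pivot coordinates are taken from it).
#' @param selection selection or id vector of pivot atoms; arity must match
#'   `kind`: 1 for inversion, 2 for rotation/translation, 3 for reflection.
#' @param kind `"inversion"`, `"rotation"`, `"translation"` or
#'   `"reflection"`.
#' @param angle rotation angle in degrees (rotation only).
#' @param multiple integer multiple of the pivot difference vector
#'   (translation only; default 1).
#' @return an object of class `"sym_op"` with fields `kind`, `Q` (3 x 3),
#'   `t` (length 3) and `pivots`.
#' @export
make_operation <- function(mol, selection, kind = c("inversion", "rotation",
                                                    "translation",
                                                    "reflection"),
                           angle = NULL, multiple = 1) {
  kind <- match.arg(kind)
  ids <- if (inherits(selection, "mol_selection")) selection$ids
         else as.integer(selection)
  P <- mol$xyz[ids, , drop = FALSE]
  need <- c(inversion = 1L, rotation = 2L, translation = 2L, reflection = 3L)
  if (length(ids) != need[[kind]])
    stop(sprintf("%s requires %d pivot(s), got %d", kind, need[[kind]],
                 length(ids)), call. = FALSE)
  op <- switch(kind,
    inversion = sym_op("inversion", -diag(3), 2 * P[1, ], P),
    rotation = {
      if (is.null(angle)) stop("rotation needs an angle", call. = FALSE)
      ax <- P[2, ] - P[1, ]
      if (vnorm(ax) < 1e-9)
        stop("coincident pivots: rotation axis undefined", call. = FALSE)
      R <- rotation_matrix(ax, angle)
      sym_op("rotation", R, P[1, ] - as.numeric(R %*% P[1, ]), P,
             angle = angle)
    },
    translation = sym_op("translation", diag(3),
                         as.numeric(multiple) * (P[2, ] - P[1, ]), P),
    reflection = {
      nrm <- crossv(P[2, ] - P[1, ], P[3, ] - P[1, ])
      if (vnorm(nrm) < 1e-9)
        stop("collinear pivots: reflection plane undefined", call. = FALSE)
      nrm <- unitv(nrm)
      Q <- diag(3) - 2 * (nrm %o% nrm)
      sym_op("reflection", Q, 2 * sum(P[1, ] * nrm) * nrm, P)
    })
  op
}

sym_op <- function(kind, Q, t, pivots = NULL, angle = NULL) {
  structure(list(kind = kind, Q = unname(Q), t = as.numeric(t),
                 pivots = pivots, angle = angle), class = "sym_op")
}

#' @export
print.sym_op <- function(x, ...) {
  cat(sprintf("symmetry operation: %s%s\n", x$kind,
              if (!is.null(x$angle)) sprintf(" (%g deg)", x$angle) else ""))
  invisible(x)
}

#' Apply a symmetry operation to coordinates
#'
#' @param op a [make_operation()] object.
#' @param xyz n x 3 matrix (or length-3 vector).
#' @return transformed coordinates, same shape.
#' @export
apply_symop <- function(op, xyz) {
  v <- is.null(dim(xyz))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  out <- sweep(xyz %*% t(op$Q), 2, op$t, `+`)
  if (v) as.numeric(out) else out
}

#' Replicate atoms through a symmetry operation
#'
#' Images of the target atoms are appended with the same element and
#' charge.  Any image landing within `threshold` of an existing atom is
#' merged with its nearest such atom (greedy nearest-first, ties broken by
#' lower atom id): the survivor moves to the average position and the
#' image is discarded.  Merging atoms of different elements is a symmetry
#' clash and errors.
#'
#' @param mol a molecule.
#' @param op a [make_operation()] operation.
#' @param targets a [mark_group()] group, id vector, or `"all"` (default:
#'   every atom).
#' @param threshold merge distance in angstrom (default 0.3).
#' @return the grown molecule.
#' @export
apply_replicate <- function(mol, op, targets = "all", threshold = 0.3) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  ids <- resolve_targets(mol, targets)
  if (length(ids) == 0L) return(mol)
  img <- apply_symop(op, mol$xyz[ids, , drop = FALSE])
  xyz <- mol$xyz
  # candidate (image, atom) pairs within threshold, chunked to bound memory
  cand <- close_pairs(img, xyz, threshold)
  used_img <- rep(FALSE, nrow(img))
  used_atom <- rep(FALSE, n_atoms(mol))
  if (nrow(cand) > 0L) {
    # greedy nearest-first; ties broken by lower atom id, then image id
    cand <- cand[order(cand[, 3], cand[, 2], cand[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_img[i] || used_atom[j]) next
      ei <- mol$element[ids[i]]; ej <- mol$element[j]
      if (ei != ej)
        stop(sprintf("symmetry clash between %s and %s", ei, ej),
             call. = FALSE)
      xyz[j, ] <- (xyz[j, ] + img[i, ]) / 2
      used_img[i] <- TRUE; used_atom[j] <- TRUE
    }
  }
  keep <- which(!used_img)
  out <- mol
  out$xyz <- xyz
  out <- sync_frame1(out)
  if (length(keep) > 0L)
    out <- add_atoms(out, mol$element[ids[keep]],
                     img[keep, , drop = FALSE], mol$charge[ids[keep]])
  if (!is.null(mol$bonds)) out$bonds <- perceive_bonds(out)
  out
}

# all (row of A, row of B, distance) pairs with distance <= threshold
close_pairs <- function(A, B, threshold, chunk = 2000L) {
  out <- list()
  bb <- rowSums(B^2)
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), bb, `+`) - 2 * Ab %*% t(B)
    hit <- which(d2 <= threshold^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) > 0L)
      out[[length(out) + 1L]] <-
        cbind(hit[, 1] + s - 1L, hit[, 2],
              sqrt(pmax(d2[hit], 0)))
  }
  if (length(out) == 0L) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, out)
}

resolve_targets <- function(mol, targets) {
  if (identical(targets, "all")) return(seq_len(n_atoms(mol)))
  if (inherits(targets, "mol_group")) return(targets$members)
  as.integer(targets)
}

#' Symmetrize atoms with respect to an order-2 operation
#'
#' For an inversion, reflection or two-fold rotation, each target atom is
#' paired with the target atom nearest to its image (possibly itself); the
#' pair is moved to the average of position and partner image, making the
#' set exactly invariant under the operation.  Atoms with no partner
#' within `threshold` are left untouched and reported.
#'
#' @inheritParams apply_replicate
#' @return the symmetrized molecule; attribute `"unmatched"` lists ids
#'   left untouched.
#' @export
symmetrize <- function(mol, op, targets = "all", threshold = 0.3) {
  if (op$kind == "translation")
    stop("symmetrize requires an order-2 point operation", call. = FALSE)
  if (op$kind == "rotation" &&
      abs(abs(((op$angle %% 360) + 360) %% 360) - 180) > 1e-9)
    stop("symmetrize rotation must be two-fold (180 degrees)",
         call. = FALSE)
  ids <- resolve_targets(mol, targets)
  img <- apply_symop(op, mol$xyz[ids, , drop = FALSE])
  xyz <- mol$xyz
  done <- rep(FALSE, length(ids))
  unmatched <- integer(0)
  for (i in seq_along(ids)) {
    if (done[i]) next
    dd <- sqrt(colSums((t(xyz[ids, , drop = FALSE]) - img[i, ])^2))
    dd[mol$element[ids] != mol$element[ids[i]]] <- Inf
    j <- which.min(dd)
    if (dd[j] > threshold) {
      unmatched <- c(unmatched, ids[i])
      done[i] <- TRUE
      next
    }
    pi_new <- (xyz[ids[i], ] + apply_symop(op, xyz[ids[j], ])) / 2
    pj_new <- (xyz[ids[j], ] + img[i, ]) / 2
    xyz[ids[i], ] <- pi_new
    xyz[ids[j], ] <- pj_new
    done[i] <- TRUE; done[j] <- TRUE
  }
  mol$xyz <- xyz
  mol <- sync_frame1(mol)
  attr(mol, "unmatched") <- unmatched
  mol
}
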