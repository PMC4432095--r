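# Orbital bookkeeping: records (symmetry, energy, occupation, subspace),
# filtering, subspace assignment and RAS-style input export, plus the
# sigma/pi classification of orbital grids by their behaviour under
# reflection through the molecular plane.

SUBSPACES <- c("frozen", "inactive", "ras1", "ras2", "ras3", "secondary",
               "deleted")
SUBSPACE_LETTER <- c(frozen = "f", inactive = "i", ras1 = "1", ras2 = "2",
                     ras3 = "3", secondary = "s", deleted = "d")

#' Construct orbital records
#'
#' @param index integer orbital indices.
#' @param symmetry irrep labels.
#' @param energy orbital energies, hartree.
#' @param occupation occupation numbers in `[0, 2]`.
#' @param subspace subspace tags from `frozen`, `inactive`, `ras1`,
#'   `ras2`, `ras3`, `secondary`, `deleted`.
#' @param hidden logical; hidden records are excluded from filtering
#'   unless requested.
#' @param grid integer references into an accompanying grid list (`NA`
#'   when the orbital has no grid).
#' @return a data frame of orbital records.
#' @export
orbital_records <- function(index, symmetry = "a", energy = 0,
                            occupation = 0, subspace = "secondary",
                            hidden = FALSE, grid = NA_integer_) {
  n <- length(index)
  rec <- data.frame(index = as.integer(index),
                    symmetry = rep_len(as.character(symmetry), n),
                    energy = rep_len(as.numeric(energy), n),
                    occupation = rep_len(as.numeric(occupation), n),
                    subspace = rep_len(as.character(subspace), n),
                    hidden = rep_len(as.logical(hidden), n),
                    grid = rep_len(as.integer(grid), n),
                    stringsAsFactors = FALSE)
  check_records(rec)
}

check_records <- function(records) {
  bad <- setdiff(unique(records$subspace), SUBSPACES)
  if (length(bad) > 0L)
    stop("unknown subspace token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(records$occupation < 0 | records$occupation > 2))
    stop("occupation must lie in [0, 2]", call. = FALSE)
  records
}

#' Filter orbital records
#'
#' Provided criteria are combined by conjunction; the original order is
#' preserved.  Hidden records are excluded unless `include_hidden`.
#' With no criteria the full visible list is returned.
#'
#' @param records orbital records ([orbital_records()]).
#' @param type orbital type label(s) to keep, matched against a `type`
#'   column (see [orbital_types()]) or the subspace tag.
#' @param symmetry irrep label(s) to keep.
#' @param energy length-2 window `[lo, hi]`, hartree.
#' @param occupation length-2 window `[lo, hi]`.
#' @param include_hidden include records flagged hidden.
#' @return the matching subset of `records`.
#' @export
filter_orbitals <- function(records, type = NULL, symmetry = NULL,
                            energy = NULL, occupation = NULL,
                            include_hidden = FALSE) {
  keep <- rep(TRUE, nrow(records))
  if (!include_hidden) keep <- keep & !records$hidden
  if (!is.null(type)) {
    have <- if (!is.null(records$type)) records$type else records$subspace
    keep <- keep & have %in% type
  }
  if (!is.null(symmetry)) keep <- keep & records$symmetry %in% symmetry
  if (!is.null(energy))
    keep <- keep & records$energy >= energy[1] & records$energy <= energy[2]
  if (!is.null(occupation))
    keep <- keep & records$occupation >= occupation[1] &
      records$occupation <= occupation[2]
  records[keep, , drop = FALSE]
}

#' Assign orbitals to a subspace
#'
#' @param records orbital records.
#' @param ids orbital `index` values to reassign (empty vector is a
#'   no-op).
#' @param subspace one subspace token.
#' @return the updated records.
#' @export
assign_subspace <- function(records, ids, subspace) {
  if (!subspace %in% SUBSPACES)
    stop("unknown subspace token: ", subspace, call. = FALSE)
  ids <- as.integer(ids)
  hit <- match(ids, records$index)
  if (anyNA(hit))
    stop("unknown orbital id(s): ",
         paste(ids[is.na(hit)], collapse = ", "), call. = FALSE)
  records$subspace[hit] <- subspace
  records
}

#' Count orbitals per subspace
#'
#' @param records orbital records.
#' @return named integer vector over all seven subspaces (summing to the
#'   number of records).
#' @export
subspace_counts <- function(records) {
  vapply(SUBSPACES, function(s) sum(records$subspace == s), 0L)
}

#' Export a RAS-style orbital-space specification
#'
#' Emits per-subspace counts per irrep (in the given irrep order) as
#' keyword lines, plus a per-orbital type-index string with one letter per
#' orbital in index order (`f` frozen, `i` inactive, `1`/`2`/`3` the RAS
#' spaces, `s` secondary, `d` deleted).  The dialect follows common
#' multiconfigurational input conventions; exactness to any particular
#' code version is not claimed.
#'
#' @param records orbital records.
#' @param symmetry_order character vector of irrep labels fixing the
#'   per-irrep count order; default: the single irrep present.
#' @return character vector of text lines (also class `"ras_spec"`).
#' @export
export_ras_spec <- function(records, symmetry_order = NULL) {
  if (is.null(symmetry_order)) {
    symmetry_order <- unique(records$symmetry)
    if (length(symmetry_order) > 1L &&
        any(is.na(records$symmetry) | !nzchar(records$symmetry)))
      stop("records with missing symmetry but several irreps present",
           call. = FALSE)
  }
  kw <- c(frozen = "Frozen", inactive = "Inactive", ras1 = "Ras1",
          ras2 = "Ras2", ras3 = "Ras3", deleted = "Deleted")
  lines <- vapply(names(kw), function(s) {
    counts <- vapply(symmetry_order, function(ir)
      sum(records$subspace == s & records$symmetry == ir), 0L)
    sprintf("%s= %s", kw[[s]], paste(counts, collapse = " "))
  }, "")
  ord <- order(records$index)
  typestr <- paste(SUBSPACE_LETTER[records$subspace[ord]], collapse = "")
  structure(c(unname(lines), sprintf("TypeIndex= %s", typestr)),
            class = c("ras_spec", "character"))
}

#' Type-index string of a RAS spec
#' @param spec an [export_ras_spec()] result.
#' @return the bare one-letter-per-orbital string.
#' @export
ras_type_string <- function(spec) {
  sub("^TypeIndex= ", "", spec[length(spec)])
}

#' Classify an orbital grid as sigma, pi or mixed
#'
#' Samples paired points (p, mirror of p through the given plane) and
#' compares amplitudes: antisymmetric (`psi(p') ~ -psi(p)`, a pi orbital
#' with respect to that plane) when at least 95 percent of the samples
#' with amplitude above the noise floor agree in magnitude and flip sign;
#' symmetric (sigma) when they agree with equal sign; mixed otherwise.
#' The noise floor is `1e-6 * max|psi|`; sampling uses a fixed internal
#' seed so the classification is deterministic.
#'
#' @param grid orbital amplitude [scalar_grid()].
#' @param point a point on the mirror plane (angstrom).
#' @param normal plane normal (need not be unit length).
#' @param n_samples number of sampled pairs (default 500).
#' @param rel_tol relative amplitude agreement tolerance (default 0.05).
#' @return `"pi"`, `"sigma"` or `"mixed"`.
#' @export
classify_plane_symmetry <- function(grid, point, normal, n_samples = 500L,
                                    rel_tol = 0.05) {
  if (vnorm(as.numeric(normal)) < 1e-12)
    stop("plane normal must be nonzero", call. = FALSE)
  nrm <- unitv(as.numeric(normal))
  maxv <- max(abs(grid$values))
  if (maxv == 0) stop("empty orbital: all amplitudes zero", call. = FALSE)
  floor_v <- 1e-6 * maxv
  # deterministic local sampling, isolated from the caller's RNG
  smp <- with_preserved_seed(20240501L, function() {
    f <- cbind(stats::runif(n_samples, 0, grid$shape[1] - 1),
               stats::runif(n_samples, 0, grid$shape[2] - 1),
               stats::runif(n_samples, 0, grid$shape[3] - 1))
    sweep(f %*% grid$axes, 2, grid$origin, `+`)
  })
  off <- sweep(smp, 2, as.numeric(point), `-`) %*% nrm
  mirrored <- smp - 2 * as.numeric(off) %o% nrm
  a <- grid_interpolate(grid, smp)
  b <- grid_interpolate(grid, mirrored)
  inside <- setdiff(seq_len(n_samples), attr(b, "clamped"))
  keep <- intersect(inside, which(abs(a) > floor_v))
  if (length(keep) < 10L)
    stop("empty orbital: too few samples above the noise floor",
         call. = FALSE)
  a <- a[keep]; b <- b[keep]
  scale <- abs(a) + abs(b)
  anti <- abs(a + b) <= rel_tol * scale
  symm <- abs(a - b) <= rel_tol * scale
  if (mean(anti) >= 0.95) "pi"
  else if (mean(symm) >= 0.95) "sigma"
  else "mixed"
}

with_preserved_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Classify every orbital in a set
#'
#' Adds a `type` column (`"sigma"`, `"pi"` or `"mixed"`) to the records of
#' an orbital set by applying [classify_plane_symmetry()] to each grid.
#'
#' @param set an [orbital_set()].
#' @param point a point on the molecular plane.
#' @param normal the plane normal.
#' @return the set with `records$type` filled in.
#' @export
orbital_types <- function(set, point, normal) {
  set$records$type <- vapply(seq_len(nrow(set$records)), function(i) {
    g <- set$records$grid[i]
    if (is.na(g)) return(NA_character_)
    classify_plane_symmetry(set$grids[[g]], point, normal)
  }, "")
  set
}

#' Bundle orbital records with their grids
#'
#' @param records orbital records ([orbital_records()]).
#' @param grids list of [scalar_grid()]s indexed by `records$grid`.
#' @return an object of class `"orbital_set"`.
#' @export
orbital_set <- function(records, grids = list()) {
  structure(list(records = check_records(records), grids = grids),
            class = "orbital_set")
}

#' @export
print.orbital_set <- function(x, ...) {
  cnt <- subspace_counts(x$records)
  cat(sprintf("orbital set: %d orbitals (%s)\n", nrow(x$records),
              paste(sprintf("%s=%d", names(cnt)[cnt > 0], cnt[cnt > 0]),
                    collapse = ", ")))
  invisible(x)
}
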