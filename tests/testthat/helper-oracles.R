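# Independent oracles used across the suite.

# brute-force all-pairs bond perception with Cordero radii
oracle_bonds <- function(mol, scale = 1.2) {
  n <- n_atoms(mol)
  out <- NULL
  for (i in seq_len(max(0, n - 1))) for (j in seq(i + 1, n)) {
    if (mol$element[i] == "X" || mol$element[j] == "X") next
    d <- sqrt(sum((mol$xyz[i, ] - mol$xyz[j, ])^2))
    if (d <= scale * (covalent_radius(mol$element[i]) +
                      covalent_radius(mol$element[j])))
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# naive double-loop electrostatic potential (hartree/e; angstrom in)
oracle_esp <- function(points, cp, q) {
  vapply(seq_len(nrow(points)), function(i) {
    d <- sqrt(rowSums(sweep(cp, 2, points[i, ], `-`)^2)) / BOHR_ANGSTROM
    sum(q / d)
  }, 0)
}

# random rigid-body motion of a molecule (rotation + translation)
random_rigid <- function(mol) {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  th <- runif(1, 0, 360)
  ct <- cos(th * pi / 180); st <- sin(th * pi / 180)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  R <- ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
  shift <- runif(3, -5, 5)
  mol$xyz <- sweep(mol$xyz %*% t(R), 2, shift, `+`)
  if (!is.null(mol$frames)) mol$frames[[1]] <- mol$xyz
  mol
}

# greedy one-to-one matching distance between two equal-size point sets
set_match_distance <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  max(vapply(seq_len(nrow(A)), function(i)
    min(sqrt(rowSums(sweep(B, 2, A[i, ], `-`)^2))), 0))
}

# the naphthalene build recipe: benzene, delete the two H on adjacent ring
# carbons 1,2, then C2 (180 deg) about the bare C-C bond, merge at 0.3 A
build_naphthalene_rotation <- function() {
  b <- make_molecule("benzene")
  m <- delete_atoms(b, c(7, 8))
  op <- make_operation(m, c(1, 2), "rotation", angle = 180)
  apply_replicate(m, op, threshold = 0.3)
}

build_naphthalene_inversion <- function() {
  b <- make_molecule("benzene")
  m <- delete_atoms(b, c(7, 8))
  m <- add_dummy(m, midpoint_of = c(1, 2))
  op <- make_operation(m, n_atoms(m), "inversion")
  out <- apply_replicate(m, op, targets = seq_len(n_atoms(m) - 1L),
                         threshold = 0.3)
  delete_atoms(out, which(out$element == "X"))
}

# |r| field sampled on [-2, 2]^3
abs_r_grid <- function(n = 33L) {
  xs <- seq(-2, 2, length.out = n)
  pts <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  scalar_grid(c(-2, -2, -2), diag(rep(4 / (n - 1), 3)),
              array(sqrt(rowSums(pts^2)), dim = c(n, n, n)),
              label = "|r|")
}
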