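# Electrostatic potential of point charges.

#' Electrostatic potential from point charges
#'
#' `V(r) = sum_i q_i / |r - r_i|` in atomic units (hartree per elementary
#' charge); positions are given in angstrom and converted to bohr
#' internally.  Evaluation is chunked over the evaluation points so the
#' distance matrix never exceeds `chunk * n_charges` entries; the result
#' is independent of the chunk size.
#'
#' @param points m x 3 evaluation positions, angstrom.
#' @param charge_positions k x 3 charge positions, angstrom.
#' @param charges length-k charges, elementary-charge units.
#' @param chunk evaluation points per block (default 1000).
#' @return numeric vector of potentials, hartree/e.
#' @export
esp_point_charges <- function(points, charge_positions, charges,
                              chunk = 1000L) {
  points <- matrix(as.numeric(points), ncol = 3) / BOHR_ANGSTROM
  cp <- matrix(as.numeric(charge_positions), ncol = 3) / BOHR_ANGSTROM
  charges <- as.numeric(charges)
  stopifnot(nrow(cp) == length(charges))
  out <- numeric(nrow(points))
  cb <- rowSums(cp^2)
  min_d <- 1e-6 / BOHR_ANGSTROM
  for (s in seq(1L, nrow(points), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(points))
    P <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(P^2), cb, `+`) - 2 * P %*% t(cp)
    d <- sqrt(pmax(d2, 0))
    if (any(d < min_d)) {
      bad <- which(d < min_d, arr.ind = TRUE)
      stop(sprintf("evaluation point %d coincides with charge %d",
                   bad[1, 1] + s - 1L, bad[1, 2]), call. = FALSE)
    }
    out[s:e] <- (1 / d) %*% charges
  }
  out
}
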