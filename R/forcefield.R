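#' Minimum-image displacement under cubic periodic boundaries
#'
#' Displacement from `a` to `b` with every component folded into
#' `[-L/2, L/2)`, so its norm is the true periodic distance.
#'
#' @param a,b Numeric 3-vectors (or matrices with 3 columns).
#' @param L Box edge (> 0).
#' @return The minimum-image displacement `b - a`.
#' @examples
#' minimum_image(c(0, 0, 0), c(49, 0, 0), L = 50)  # c(-1, 0, 0)
#' @export
minimum_image <- function(a, b, L) {
  stopifnot_scalar(L, "L", positive = TRUE)
  d <- b - a
  d - L * floor(d / L + 0.5)
}

#' Harmonic bond energy
#'
#' \eqn{E = \frac{1}{2} k (r - r_0)^2} with stiffness `k` = 330 kT/sigma^2
#' and rest length `r0` = 1.2 sigma by default.
#'
#' @param r Center-to-center distance(s), >= 0.
#' @param k Spring stiffness.
#' @param r0 Rest length.
#' @return Energy in kT.
#' @examples
#' bond_energy(1.3)  # 1.65
#' @export
bond_energy <- function(r, k = 330, r0 = 1.2) {
  if (any(r < 0)) stop("'r' must be >= 0")
  0.5 * k * (r - r0)^2
}

#' Truncated Lennard-Jones pair energy
#'
#' \eqn{E_{ij}(r) = 4\varepsilon_{ij}[(\sigma/r)^{12} - \xi_{ij}(\sigma/r)^6]}
#' for `r < r_cut`, and exactly 0 beyond. Truncation is unshifted by
#' default, leaving a small discontinuity of
#' \eqn{4\varepsilon(3^{-12} - \xi\, 3^{-6})} at the cutoff; `shift = TRUE`
#' subtracts the cutoff value instead.
#'
#' @param r Distance(s) in sigma units, > 0.
#' @param eps Well parameter \eqn{\varepsilon_{ij}} in kT.
#' @param xi Attraction switch, 0 or 1.
#' @param sigma Length scale (default 1).
#' @param r_cut Cutoff distance (default `3 * sigma`).
#' @param shift Shift the energy to zero at the cutoff (default `FALSE`).
#' @return Energy in kT.
#' @examples
#' lj_pair_energy(2^(1 / 6), eps = 1, xi = 1)  # -1
#' @export
lj_pair_energy <- function(r, eps, xi, sigma = 1, r_cut = 3 * sigma,
                           shift = FALSE) {
  if (any(r <= 0)) stop("'r' must be > 0 (overlap singularity at r = 0)")
  sr6 <- (sigma / r)^6
  e <- 4 * eps * (sr6^2 - xi * sr6)
  if (shift) {
    sc6 <- (sigma / r_cut)^6
    e <- e - 4 * eps * (sc6^2 - xi * sc6)
  }
  e[r >= r_cut] <- 0
  e
}

#' Total forces on every particle
#'
#' Negative gradient of the total energy (harmonic bonds plus truncated
#' Lennard-Jones pairs) under periodic boundaries. Forces obey Newton's
#' third law and sum to zero. A pair distance below 0.3 sigma is treated as
#' an unstable configuration and raises an error.
#'
#' @param state A `sim_state` (see [build_initial_state()]).
#' @param topology The matching [build_topology()] object (for the bond
#'   list); may be `NULL` for bond-free systems.
#' @param table A [make_interaction_table()] object.
#' @return An n x 3 matrix of forces in kT/sigma.
#' @export
total_forces <- function(state, topology, table) {
  bonds <- if (is.null(topology)) {
    matrix(integer(0), 0, 2)
  } else {
    topology$bonds - 1L
  }
  .forces_cpp(state$positions, species_code(state$species), bonds,
              table$eps, table$xi, state$box_edge, table$r_cut,
              table$k_bond, table$r0)
}

#' Total potential energy of a configuration
#'
#' All-pairs evaluation of the bonded plus non-bonded energy; intended for
#' small systems and validation (the engine itself uses neighbor lists).
#'
#' @inheritParams total_forces
#' @return Scalar energy in kT.
#' @export
total_energy <- function(state, topology, table) {
  bonds <- if (is.null(topology)) {
    matrix(integer(0), 0, 2)
  } else {
    topology$bonds - 1L
  }
  .energy_cpp(state$positions, species_code(state$species), bonds,
              table$eps, table$xi, state$box_edge, table$r_cut,
              table$k_bond, table$r0)
}

#' Interacting pairs found by the cell/Verlet list
#'
#' Exposes the neighbor-search machinery for validation: all unordered
#' pairs with minimum-image distance strictly below `cutoff`.
#'
#' @param positions n x 3 coordinate matrix.
#' @param L Box edge.
#' @param cutoff Pair distance cutoff.
#' @return Two-column integer matrix of 1-based pair indices (i < j).
#' @export
interacting_pairs <- function(positions, L, cutoff) {
  .neighbor_pairs_cpp(positions, L, cutoff)
}
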