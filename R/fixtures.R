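#' Deterministic hand-placed fixture configurations
#'
#' Small geometries with analytically known contact structure, used for
#' exact analysis tests and for the loop-traffic assay:
#'
#' * `"two-monomer"`: two bonded monomers 1.5 sigma apart - exactly one
#'   intra-polymer contact at the default threshold.
#' * `"single-loop"`: an open chain whose two anchor monomers are held
#'   1.5 sigma apart, closing a circular loop between two diverging tails.
#'   The contact matrix has a single long-range off-diagonal entry; tracers
#'   diffusing over this frozen scaffold accumulate at the contact point.
#'   Attributes `"contact_monomers"` (anchors with their chain neighbors)
#'   and `"interior_monomers"` (tail interiors, far from the contact) mark
#'   the regions compared by [loop_traffic_ratio()].
#' * `"globule-shell"`: a dense ball of monomers on a cubic lattice with a
#'   known surface set (attribute `"surface_monomers"`), for coverage and
#'   exclusion tests. Its chain ordering is geometric, not dynamical.
#'
#' @param name Fixture name.
#' @return A `sim_trajectory` with one snapshot and fixture attributes
#'   (including `"topology"`).
#' @export
make_fixture <- function(name = c("single-loop", "two-monomer",
                                  "globule-shell")) {
  name <- match.arg(name)
  if (name == "two-monomer") {
    L <- 50
    pos <- rbind(c(10, 10, 10), c(11.5, 10, 10))
    topo <- fixture_topology(2L, anchors = integer(0))
    return(fixture_trajectory(pos, c("p", "p"), L, topo))
  }
  if (name == "single-loop") {
    L <- 60
    N <- 100L
    spacing <- 1.2
    i_a <- 30L
    i_b <- 71L
    gap <- 1.5
    anchor_a <- c(0, gap / 2, 0)
    anchor_b <- c(0, -gap / 2, 0)
    n_arc <- i_b - i_a - 1L  # monomers strictly between the anchors
    arc_len <- (n_arc + 1L) * spacing
    delta <- 2 * pi - 2 * asin((gap / 2) / (arc_len / (2 * pi - 0.2)))
    # circle through both anchors, bulging into x > 0
    R <- arc_len / delta
    cx <- sqrt(max(R^2 - (gap / 2)^2, 0))
    ang_a <- atan2(anchor_a[2], anchor_a[1] - cx)   # ~ pi - small
    ang_b <- atan2(anchor_b[2], anchor_b[1] - cx)   # ~ -pi + small
    # sweep from ang_a down through 0 to ang_b
    angles <- seq(ang_a, ang_b, length.out = n_arc + 2L)
    arc <- cbind(cx + R * cos(angles), R * sin(angles), 0)
    dir_a <- c(-cos(25 * pi / 180), sin(25 * pi / 180), 0)
    dir_b <- c(-cos(25 * pi / 180), -sin(25 * pi / 180), 0)
    tail_a <- t(vapply(seq_len(i_a - 1L), function(k) {
      anchor_a + (i_a - k) * spacing * dir_a
    }, numeric(3)))
    tail_b <- t(vapply(seq_len(N - i_b), function(k) {
      anchor_b + k * spacing * dir_b
    }, numeric(3)))
    pos <- rbind(tail_a, arc, tail_b) + matrix(rep(L / 2, 3), N, 3,
                                               byrow = TRUE)
    topo <- fixture_topology(N, anchors = c(i_a, i_b))
    traj <- fixture_trajectory(pos, ifelse(seq_len(N) %in% c(i_a, i_b),
                                           "a", "p"), L, topo)
    attr(traj, "contact_monomers") <- c(i_a - 1L, i_a, i_a + 1L,
                                        i_b - 1L, i_b, i_b + 1L)
    attr(traj, "interior_monomers") <- c(5:22, 79:96)
    return(traj)
  }
  # globule-shell
  L <- 50
  spacing <- 1.1
  R <- 4
  grid <- expand.grid(x = seq(-R, R, by = spacing),
                      y = seq(-R, R, by = spacing),
                      z = seq(-R, R, by = spacing))
  rad <- sqrt(rowSums(grid^2))
  keep <- rad <= R
  grid <- grid[keep, ]
  rad <- rad[keep]
  ord <- order(rad)
  pos <- as.matrix(grid[ord, ]) + L / 2
  rad <- rad[ord]
  N <- nrow(pos)
  topo <- fixture_topology(N, anchors = integer(0))
  traj <- fixture_trajectory(pos, rep("p", N), L, topo)
  attr(traj, "surface_monomers") <- which(rad > R - spacing)
  traj
}

fixture_topology <- function(N, anchors) {
  structure(
    list(N = as.integer(N), phi = length(anchors) / N,
         anchor_indices = as.integer(anchors),
         bonds = if (N > 1) cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L)
                 else matrix(integer(0), 0, 2),
         seed = 0L),
    class = "polymer_topology")
}

fixture_trajectory <- function(pos, species, L, topo) {
  pos <- pos - L * floor(pos / L)
  coords <- array(pos, c(nrow(pos), 3, 1))
  cfg <- structure(
    list(topology = topo, table = make_interaction_table(0),
         epsilon = 0, n_tracers = 0L,
         n_binders = 0L, L = L, dt = 0.005, gamma = 1, kT = 1,
         n_total = 1, n_equil = 0, sample_every = 1, seed = 0L,
         integrator = "baoab"),
    class = "sim_config")
  structure(
    list(coords = coords, species = species, box_edge = L,
         steps = 0L, config = cfg, fixed_polymer = TRUE,
         diagnostics = NULL,
         final_state = sim_state(pos, species, L),
         provenance = list(package = "chromotracer",
                           version = as.character(
                             packageVersion("chromotracer")),
                           seed = 0L)),
    class = "sim_trajectory")
}

#' Traffic enhancement at a loop contact point
#'
#' Ratio of the mean tracer traffic over the fixture's contact-region
#' monomers to the mean over its chain-interior monomers.
#'
#' @param tp A [traffic_profile()] computed from a tracer run over the
#'   `"single-loop"` fixture.
#' @param fixture The fixture the run used (source of the region
#'   attributes).
#' @return Scalar ratio.
#' @export
loop_traffic_ratio <- function(tp, fixture) {
  contact <- attr(fixture, "contact_monomers")
  interior <- attr(fixture, "interior_monomers")
  if (is.null(contact) || is.null(interior)) {
    stop("fixture carries no contact/interior region annotation")
  }
  mean(tp$C[contact]) / mean(tp$C[interior])
}
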