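#' Species labels of the model
#'
#' The model has exactly four particle species: `p` (ordinary polymer
#' monomer), `a` (anchor monomer, a binder binding site), `b` (diffusible
#' binder) and `t` (diffusible tracer). The species of a particle determines
#' only which row/column of the interaction table applies to it.
#'
#' @return Character vector `c("p", "a", "b", "t")`.
#' @export
species_levels <- function() SPECIES

#' Build the per-species-pair interaction table
#'
#' All particle pairs interact through a truncated Lennard-Jones potential
#' \deqn{E_{ij}(r) = 4\varepsilon_{ij}[(\sigma/r)^{12} - \xi_{ij}(\sigma/r)^6]}
#' cut off at `r_cut`. The switch \eqn{\xi_{ij} \in \{0,1\}} selects between
#' pure hard-core repulsion (0) and an attractive well of depth
#' \eqn{\varepsilon_{ij}} (1). Binders attract anchors with a fixed strong
#' energy `epsilon_anchor` (default 10 kT, deep enough that bridges are
#' effectively permanent); tracers attract the whole polymer (both `p` and
#' `a`) with the sweep parameter `epsilon_tracer`. Every other pair, notably
#' binder-tracer, is hard-core only. Consecutive monomers are additionally
#' connected by harmonic springs of stiffness `k_bond` and rest length `r0`.
#'
#' @param epsilon_tracer Non-specific tracer-polymer affinity in kT units
#'   (\eqn{\varepsilon \equiv \varepsilon_{tp} \equiv \varepsilon_{ta}}).
#'   `0` turns the tracer attraction off entirely (hard-core control).
#' @param epsilon_anchor Binder-anchor well depth in kT (default 10).
#' @param sigma Particle diameter scale; the simulation length unit
#'   (physically about 15 nm, metadata only).
#' @param r_cut Lennard-Jones cutoff (default `3 * sigma`). The potential is
#'   truncated without shifting; an `energy_shift` flag is accepted for
#'   sensitivity checks but defaults off.
#' @param k_bond Bond spring stiffness in kT/sigma^2 (default 330).
#' @param r0 Bond rest length (default `1.2 * sigma`).
#' @param hardcore_eps Repulsion amplitude used for pairs with
#'   \eqn{\xi_{ij} = 0} (default 1 kT).
#' @param energy_shift Logical; if `TRUE` energies reported by
#'   [lj_pair_energy()] are shifted to zero at the cutoff. Defaults to
#'   `FALSE` (plain truncation).
#' @return An object of class `interaction_table` with symmetric 4x4
#'   matrices `eps` and `xi` (dimnames `p`, `a`, `b`, `t`) and the scalar
#'   constants.
#' @examples
#' tab <- make_interaction_table(1.5)
#' tab$eps["t", "p"]  # 1.5
#' tab$xi["b", "t"]   # 0: binders and tracers are mutually hard-core
#' @export
make_interaction_table <- function(epsilon_tracer,
                                   epsilon_anchor = 10,
                                   sigma = 1,
                                   r_cut = 3 * sigma,
                                   k_bond = 330,
                                   r0 = 1.2 * sigma,
                                   hardcore_eps = 1,
                                   energy_shift = FALSE) {
  stopifnot_scalar(epsilon_tracer, "epsilon_tracer")
  if (epsilon_tracer < 0) stop("'epsilon_tracer' must be >= 0")
  stopifnot_scalar(epsilon_anchor, "epsilon_anchor", positive = TRUE)
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  stopifnot_scalar(r_cut, "r_cut", positive = TRUE)
  if (r_cut <= r0) stop("'r_cut' must exceed the bond rest length 'r0'")

  eps <- matrix(hardcore_eps, 4, 4, dimnames = list(SPECIES, SPECIES))
  xi <- matrix(0, 4, 4, dimnames = list(SPECIES, SPECIES))
  eps["a", "b"] <- eps["b", "a"] <- epsilon_anchor
  xi["a", "b"] <- xi["b", "a"] <- 1
  if (epsilon_tracer > 0) {
    eps["t", "p"] <- eps["p", "t"] <- epsilon_tracer
    eps["t", "a"] <- eps["a", "t"] <- epsilon_tracer
    xi["t", "p"] <- xi["p", "t"] <- 1
    xi["t", "a"] <- xi["a", "t"] <- 1
  }
  structure(
    list(eps = eps, xi = xi, sigma = sigma, r_cut = r_cut, k_bond = k_bond,
         r0 = r0, epsilon_tracer = epsilon_tracer,
         epsilon_anchor = epsilon_anchor, hardcore_eps = hardcore_eps,
         energy_shift = isTRUE(energy_shift)),
    class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("Interaction table (kT units, sigma = ", x$sigma, ")\n", sep = "")
  cat("  tracer epsilon:", x$epsilon_tracer,
      "| binder-anchor epsilon:", x$epsilon_anchor, "\n")
  cat("  r_cut:", x$r_cut, "| k_bond:", x$k_bond, "| r0:", x$r0, "\n")
  invisible(x)
}

#' Build a looped-polymer topology
#'
#' Constructs a single unbranched bead-spring chain of `N` monomers with
#' `round(phi * N)` anchor monomers drawn uniformly at random without
#' replacement. Each replicate of a simulation campaign uses a different
#' anchor placement, so the anchor draw is seeded explicitly.
#'
#' @param N Total number of monomers (>= 2).
#' @param phi Anchor fraction in (0, 1].
#' @param seed Integer seed for the anchor draw.
#' @return An object of class `polymer_topology`: list with `N`, `phi`,
#'   `anchor_indices` (sorted), `bonds` (an `(N-1) x 2` matrix of consecutive
#'   pairs) and `seed`.
#' @examples
#' top <- build_topology(100, 0.02, seed = 1)
#' length(top$anchor_indices)  # 2
#' nrow(top$bonds)             # 99
#' @export
build_topology <- function(N, phi, seed) {
  stopifnot_scalar(N, "N")
  stopifnot_scalar(phi, "phi")
  if (N < 2 || N != round(N)) stop("'N' must be an integer >= 2")
  if (phi <= 0 || phi > 1) stop("'phi' must be in (0, 1]")
  n_anchor <- round(phi * N)
  if (n_anchor == 0) {
    stop("round(phi * N) is zero: no anchors, no loops possible")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  anchors <- sort(sample.int(N, n_anchor))
  structure(
    list(N = as.integer(N), phi = phi,
         anchor_indices = as.integer(anchors),
         bonds = cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L),
         seed = as.integer(seed)),
    class = "polymer_topology")
}

#' @export
print.polymer_topology <- function(x, ...) {
  cat("Polymer topology: N =", x$N, ", phi =", x$phi,
      "(", length(x$anchor_indices), "anchors ),", nrow(x$bonds), "bonds\n")
  invisible(x)
}

# save/restore the global RNG state so seeded constructors do not perturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Anchor-fraction and affinity grids of the full study design
#'
#' The full simulation design crosses 25 anchor fractions (2\% to 50\% in
#' steps of 2\%) with 10 tracer affinities (0.9 to 2.7 kT in steps of
#' 0.2 kT), ten replicates each. Desk-scale work uses subsets.
#'
#' @return Numeric vector of parameter values.
#' @export
phi_grid <- function() round(seq(0.02, 0.50, by = 0.02), 10)

#' @rdname phi_grid
#' @export
epsilon_grid <- function() round(seq(0.9, 2.7, by = 0.2), 10)

#' Assemble a simulation configuration
#'
#' Bundles the topology, interaction table and run protocol. The number of
#' binders is fixed by the stoichiometry of the model: two binders per
#' anchor monomer, `n_binders = 2 * phi * N`.
#'
#' @param topology A [build_topology()] object.
#' @param epsilon Tracer-polymer affinity in kT; used to build the
#'   interaction table unless `table` is supplied.
#' @param n_tracers Number of tracer particles.
#' @param L Cubic box edge in sigma units (default 50).
#' @param dt Integration timestep in simulation units (default 0.005 for the
#'   default BAOAB scheme; use ~1e-4 scale values for the Brownian scheme).
#' @param gamma Drag coefficient (default 1).
#' @param kT Thermal energy (default 1; defines the energy unit).
#' @param n_total Total number of MD steps.
#' @param n_equil Equilibration steps discarded before sampling.
#' @param sample_every Snapshot interval; must divide `n_total - n_equil`.
#' @param seed Integer seed governing building and dynamics.
#' @param integrator `"baoab"` (underdamped, default) or `"brownian"`
#'   (overdamped Euler-Maruyama).
#' @param table Optional [make_interaction_table()] object overriding
#'   `epsilon`.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(topology, epsilon, n_tracers,
                              L = 50, dt = 0.005, gamma = 1, kT = 1,
                              n_total = 3e5, n_equil = 1e5,
                              sample_every = 100, seed = 1,
                              integrator = c("baoab", "brownian"),
                              table = NULL) {
  if (!inherits(topology, "polymer_topology")) {
    stop("'topology' must be a polymer_topology object")
  }
  integrator <- match.arg(integrator)
  if (is.null(table)) table <- make_interaction_table(epsilon)
  stopifnot_scalar(L, "L", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(n_tracers, "n_tracers")
  if (n_tracers < 0) stop("'n_tracers' must be >= 0")
  if (n_equil >= n_total) stop("'n_equil' must be smaller than 'n_total'")
  if ((n_total - n_equil) %% sample_every != 0) {
    stop("'sample_every' must divide the sampling window n_total - n_equil")
  }
  n_binders <- 2L * length(topology$anchor_indices)
  structure(
    list(topology = topology, table = table,
         epsilon = table$epsilon_tracer,
         n_tracers = as.integer(n_tracers), n_binders = n_binders,
         L = L, dt = dt, gamma = gamma, kT = kT,
         n_total = n_total, n_equil = n_equil,
         sample_every = sample_every, seed = as.integer(seed),
         integrator = integrator),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: N =", x$topology$N, ", phi =", x$topology$phi,
      ", epsilon =", x$epsilon, "\n")
  cat("  binders:", x$n_binders, "| tracers:", x$n_tracers,
      "| box L =", x$L, "\n")
  cat("  steps:", format(x$n_total, scientific = FALSE),
      "( equil", format(x$n_equil, scientific = FALSE),
      ", sample every", x$sample_every, ") dt =", x$dt,
      "scheme =", x$integrator, "\n")
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Accepts a YAML (or flat `key: value`) file with any of the fields `N`,
#' `phi`, `epsilon`, `n_tracers`, `L`, `dt`, `n_equil`, `n_total`,
#' `sample_every`, `seed`, `integrator`, `fixed_polymer`,
#' `epsilon_zero_control` and returns a [simulation_config()] plus run
#' flags.
#'
#' @param path Path to the config file.
#' @return A list with elements `config` (a `sim_config`) and `flags`
#'   (list with `fixed_polymer`, `epsilon_zero_control`).
#' @export
read_config <- function(path) {
  # keep single-letter keys like N literal (YAML 1.1 would read them as
  # booleans) while still resolving true/false flag values
  keep_letters <- c("y", "Y", "n", "N")
  handlers <- list(
    "bool#yes" = function(x) if (x %in% keep_letters) x else TRUE,
    "bool#no" = function(x) if (x %in% keep_letters) x else FALSE)
  vals <- yaml::yaml.load(paste(readLines(path, warn = FALSE),
                                collapse = "\n"),
                          handlers = handlers)
  need <- function(key, default = NULL) {
    if (!is.null(vals[[key]])) vals[[key]]
    else if (!is.null(default)) default
    else stop("config file is missing required key '", key, "'")
  }
  epsilon <- need("epsilon")
  if (isTRUE(vals$epsilon_zero_control)) epsilon <- 0
  topo <- build_topology(need("N"), need("phi"),
                         seed = as.integer(need("seed", 1)))
  cfg <- simulation_config(
    topo, epsilon = epsilon, n_tracers = need("n_tracers"),
    L = need("L", 50), dt = need("dt", 0.005),
    n_total = need("n_total", 3e5), n_equil = need("n_equil", 1e5),
    sample_every = need("sample_every", 100),
    seed = as.integer(need("seed", 1)),
    integrator = need("integrator", "baoab"))
  list(config = cfg,
       flags = list(fixed_polymer = isTRUE(vals$fixed_polymer),
                    epsilon_zero_control = isTRUE(vals$epsilon_zero_control)))
}
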