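#' Run a Langevin simulation
#'
#' Builds (or accepts) an initial configuration, integrates `n_total` steps
#' of Langevin dynamics at constant temperature, discards the first
#' `n_equil` steps and collects a snapshot every `sample_every` steps.
#' The default scheme is underdamped BAOAB with unit mass; the overdamped
#' Euler-Maruyama (`"brownian"`) scheme is available for free-diffusion
#' checks and relaxation. Runs are fully reproducible from `config$seed`.
#'
#' With `fixed_polymer = TRUE` the polymer and binder particles are frozen
#' in place and only the tracers move - the hard-core control used to
#' isolate volume-exclusion effects. In that case an equilibrated
#' polymer+binder configuration should be supplied via `initial_state`.
#'
#' @param config A [simulation_config()].
#' @param fixed_polymer Freeze all `p`, `a` and `b` particles.
#' @param initial_state Optional `sim_state` to start from (default: built
#'   and relaxed from scratch, then equilibrated as part of the run).
#' @return A `sim_trajectory`: list with `coords` (n x 3 x S array of
#'   wrapped coordinates), `species`, `box_edge`, `steps`, `config`,
#'   `diagnostics` and `provenance`.
#' @export
run_simulation <- function(config, fixed_polymer = FALSE,
                           initial_state = NULL) {
  state <- initial_state %||% build_initial_state(config)
  n <- nrow(state$positions)
  mobile <- rep(TRUE, n)
  if (fixed_polymer) mobile <- state$species == "t"
  res <- .engine_call(state, config, n_total = config$n_total,
                      n_equil = config$n_equil,
                      sample_every = config$sample_every, mobile = mobile)
  new_trajectory(res, state, config,
                 fixed_polymer = fixed_polymer)
}

new_trajectory <- function(res, state, config, fixed_polymer = FALSE) {
  structure(
    list(coords = res$snapshots,
         species = state$species,
         box_edge = config$L,
         steps = res$snapshot_steps,
         config = config,
         fixed_polymer = fixed_polymer,
         diagnostics = res$diagnostics,
         final_state = sim_state(res$final_positions, state$species,
                                 config$L, step = config$n_total),
         provenance = list(
           package = "chromotracer",
           version = as.character(packageVersion("chromotracer")),
           seed = config$seed)),
    class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat("Trajectory:", n_snapshots(x), "snapshots of",
      length(x$species), "particles ( N =", x$config$topology$N,
      ", phi =", x$config$topology$phi, ", epsilon =", x$config$epsilon,
      ")\n")
  cat("  seed", x$provenance$seed,
      if (isTRUE(x$fixed_polymer)) "| fixed polymer" else "", "\n")
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param traj A `sim_trajectory`.
#' @return Integer snapshot count.
#' @export
n_snapshots <- function(traj) {
  d <- dim(traj$coords)
  if (is.null(d)) 0L else d[3]
}

#' Simulate tracers diffusing over a frozen scaffold
#'
#' Takes any configuration (an equilibrated polymer+binder state, or a
#' hand-built fixture), freezes every non-tracer particle, adds `n_tracers`
#' freshly placed tracers and integrates only their motion. Used for the
#' hard-core-control comparison and the loop-fixture assay.
#'
#' @param scaffold A `sim_state` whose `p`/`a`/`b` particles define the
#'   frozen scaffold (existing tracers are dropped).
#' @param topology The matching polymer topology.
#' @param epsilon Tracer-polymer affinity (0 = hard-core only).
#' @param n_tracers Number of tracers to add.
#' @param seed Integer seed.
#' @param n_total,n_equil,sample_every Run protocol (defaults 3e5 / 1e5 /
#'   100).
#' @param dt,integrator Passed to [simulation_config()].
#' @return A `sim_trajectory` with `fixed_polymer = TRUE`.
#' @export
run_tracers_on_state <- function(scaffold, topology, epsilon, n_tracers,
                                 seed, n_total = 3e5, n_equil = 1e5,
                                 sample_every = 100, dt = 0.005,
                                 integrator = "baoab") {
  keep <- scaffold$species != "t"
  base_pos <- scaffold$positions[keep, , drop = FALSE]
  base_sp <- scaffold$species[keep]
  L <- scaffold$box_edge
  n_binders <- sum(base_sp == "b")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pos <- base_pos
  for (k in seq_len(n_tracers)) {
    for (try in 1:10000) {
      cand <- runif(3, 0, L)
      d <- minimum_image(pos, matrix(cand, nrow(pos), 3, byrow = TRUE), L)
      if (all(rowSums(d^2) >= 0.9^2)) {
        pos <- rbind(pos, cand)
        break
      }
      if (try == 10000) stop("tracer placement failed")
    }
  }
  state <- sim_state(pos, c(base_sp, rep("t", n_tracers)), L)
  cfg <- simulation_config(topology, epsilon = epsilon,
                           n_tracers = n_tracers, L = L, dt = dt,
                           n_total = n_total, n_equil = n_equil,
                           sample_every = sample_every, seed = seed,
                           integrator = integrator)
  # align the declared binder count with the scaffold
  cfg$n_binders <- n_binders
  res <- .engine_call(state, cfg, n_total = n_total, n_equil = n_equil,
                      sample_every = sample_every,
                      mobile = state$species == "t")
  new_trajectory(res, state, cfg, fixed_polymer = TRUE)
}
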