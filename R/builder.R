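#' Construct a system state
#'
#' Low-level constructor for a `sim_state`: coordinates, species labels and
#' box. Particle order is the package-wide contract: monomers first (in
#' chain order), then binders, then tracers.
#'
#' @param positions n x 3 numeric matrix in sigma units.
#' @param species Character vector of labels in `{p, a, b, t}`.
#' @param box_edge Box edge L.
#' @param step Integer time index (default 0).
#' @return A `sim_state` object.
#' @export
sim_state <- function(positions, species, box_edge, step = 0L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("'positions' must have 3 columns")
  if (nrow(positions) != length(species)) {
    stop("positions and species lengths differ")
  }
  species_code(species)  # validates labels
  stopifnot_scalar(box_edge, "box_edge", positive = TRUE)
  positions <- positions - box_edge * floor(positions / box_edge)
  structure(list(positions = positions, species = as.character(species),
                 box_edge = box_edge, step = as.integer(step)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat("System state:", nrow(x$positions), "particles (",
      paste(sprintf("%s:%d", names(table(x$species)), table(x$species)),
            collapse = " "),
      ") in box L =", x$box_edge, "at step", x$step, "\n")
  invisible(x)
}

monomer_indices <- function(state) which(state$species %in% c("p", "a"))
tracer_indices <- function(state) which(state$species == "t")
binder_indices <- function(state) which(state$species == "b")

species_from_config <- function(config) {
  topo <- config$topology
  sp <- rep("p", topo$N)
  sp[topo$anchor_indices] <- "a"
  c(sp, rep("b", config$n_binders), rep("t", config$n_tracers))
}

#' Build an initial configuration
#'
#' Places the polymer as a self-avoiding-ish random walk (step length `r0`,
#' rejecting proposals closer than 0.9 sigma to previously placed
#' monomers), then scatters binders and tracers uniformly in the box while
#' avoiding sub-0.9-sigma overlaps, and finally runs a short capped-force
#' Brownian relaxation to soften residual contacts. The relaxation never
#' alters the topology. All placement randomness derives from
#' `config$seed`, so builds are reproducible bit-exactly.
#'
#' @param config A [simulation_config()] object.
#' @param relax_steps Capped-force relaxation steps (default 2000; `0`
#'   skips relaxation, leaving bonded neighbors exactly at `r0`).
#' @return A `sim_state` with attribute `"relaxed"`.
#' @export
build_initial_state <- function(config, relax_steps = 2000) {
  topo <- config$topology
  L <- config$L
  r0 <- config$table$r0
  min_sep <- 0.9
  n_total <- topo$N + config$n_binders + config$n_tracers
  vol_frac <- n_total * (4 / 3) * pi * 0.5^3 / L^3
  if (vol_frac >= 0.3) {
    stop("box too small: hard-core volume fraction ", round(vol_frac, 2),
         " >= 0.3")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  pos <- matrix(NA_real_, n_total, 3)
  pos[1, ] <- runif(3, 0, L)
  for (i in seq_len(topo$N)[-1]) {
    placed <- FALSE
    for (try in 1:500) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1, ] + r0 * u
      prev <- pos[seq_len(i - 2), , drop = FALSE]
      ok <- TRUE
      if (nrow(prev)) {
        d <- minimum_image(prev, matrix(cand, nrow(prev), 3, byrow = TRUE), L)
        ok <- all(rowSums(d^2) >= min_sep^2)
      }
      if (ok) {
        pos[i, ] <- cand %% L
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("chain placement failed at monomer ", i)
  }
  for (i in topo$N + seq_len(config$n_binders + config$n_tracers)) {
    placed <- FALSE
    for (try in 1:10000) {
      cand <- runif(3, 0, L)
      prev <- pos[seq_len(i - 1), , drop = FALSE]
      d <- minimum_image(prev, matrix(cand, nrow(prev), 3, byrow = TRUE), L)
      if (all(rowSums(d^2) >= min_sep^2)) {
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("free-particle placement failed at particle ", i)
  }

  state <- sim_state(pos, species_from_config(config), L)
  if (relax_steps > 0) {
    res <- .engine_call(state, config, n_total = relax_steps,
                        n_equil = relax_steps, sample_every = relax_steps,
                        mobile = rep(TRUE, n_total),
                        scheme = "brownian", dt = 5e-4,
                        force_cap = 50, seed_offset = 777L)
    state$positions <- res$final_positions
    close_pairs <- interacting_pairs(state$positions, L, 0.8)
    if (nrow(close_pairs) > 0) {
      d2 <- rowSums(minimum_image(
        state$positions[close_pairs[, 1], , drop = FALSE],
        state$positions[close_pairs[, 2], , drop = FALSE], L)^2)
      nonbonded <- abs(close_pairs[, 1] - close_pairs[, 2]) > 1 |
        close_pairs[, 1] > topo$N | close_pairs[, 2] > topo$N
      if (any(nonbonded & d2 < 0.8^2)) {
        stop("relaxation left non-bonded pairs below 0.8 sigma")
      }
    }
  }
  attr(state, "relaxed") <- relax_steps > 0
  state
}

# shared wrapper around the C++ engine
.engine_call <- function(state, config, n_total, n_equil, sample_every,
                         mobile, scheme = config$integrator, dt = config$dt,
                         force_cap = 0, drift_cap = 0.3, seed_offset = 0L,
                         diag_every = 1000L) {
  tab <- config$table
  topo <- config$topology
  chain <- seq_len(topo$N)
  .run_engine_cpp(
    state$positions, species_code(state$species), topo$bonds - 1L,
    tab$eps, tab$xi, config$L, tab$r_cut, tab$k_bond, tab$r0,
    dt, config$gamma, config$kT,
    n_total, n_equil, sample_every,
    mobile, skin = 0.4,
    seed = (config$seed + seed_offset) %% 2147483647,
    scheme = scheme, force_cap = force_cap,
    drift_cap = if (scheme == "brownian") drift_cap else 0,
    chain_idx = chain, diag_every = as.integer(diag_every))
}

#' Equilibrate a state
#'
#' Advances the system by `config$n_equil` steps without sampling and
#' attaches a stationarity diagnostic: the relative drift of the running
#' mean of the polymer radius of gyration over the last 20\% of the
#' equilibration window.
#'
#' @param state A `sim_state`.
#' @param config A [simulation_config()].
#' @param mobile Optional logical mask; `FALSE` entries are frozen.
#' @return The equilibrated `sim_state`, with attribute
#'   `"stationarity"` (list with `rg_series`, `rel_drift`).
#' @export
equilibrate <- function(state, config, mobile = NULL) {
  n <- nrow(state$positions)
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  res <- .engine_call(state, config, n_total = config$n_equil,
                      n_equil = config$n_equil,
                      sample_every = config$n_equil, mobile = mobile,
                      seed_offset = 555L)
  out <- state
  out$positions <- res$final_positions
  out$step <- as.integer(config$n_equil)
  rg <- res$diagnostics$r_gyr
  drift <- NA_real_
  if (length(rg) >= 10) {
    k <- length(rg)
    tail20 <- rg[seq.int(ceiling(0.8 * k), k)]
    half <- length(tail20) %/% 2
    m1 <- mean(tail20[seq_len(half)])
    m2 <- mean(tail20[-seq_len(half)])
    drift <- abs(m2 - m1) / max(m1, 1e-12)
  }
  attr(out, "stationarity") <- list(rg_series = rg, rel_drift = drift)
  out
}
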