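#' Plan a (phi, epsilon) simulation sweep
#'
#' The full study design crosses [phi_grid()] x [epsilon_grid()] with ten
#' replicates (2500 runs); the `"desk"` profile is any subset at scaled
#' step counts. Every cell receives a deterministic seed derived from
#' `(base_seed, phi, epsilon, replicate)` so grids are byte-identical
#' across reruns regardless of execution order.
#'
#' @param phi_values,epsilon_values Parameter values of the sweep.
#' @param n_replicates Replicates per cell (full design: 10).
#' @param base_seed Integer base seed.
#' @param profile `"desk"` or `"paper-scale"` (metadata only).
#' @return An object of class `sweep_plan` with a `cells` data frame.
#' @export
sweep_plan <- function(phi_values, epsilon_values, n_replicates = 3,
                       base_seed = 1, profile = c("desk", "paper-scale")) {
  profile <- match.arg(profile)
  cells <- expand.grid(replicate = seq_len(n_replicates),
                       epsilon = epsilon_values, phi = phi_values,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("phi", "epsilon", "replicate")]
  cells$seed <- mapply(mix_seed, base_seed, cells$phi, cells$epsilon,
                       cells$replicate)
  structure(list(cells = cells, base_seed = as.integer(base_seed),
                 n_replicates = n_replicates, profile = profile),
            class = "sweep_plan")
}

#' @export
print.sweep_plan <- function(x, ...) {
  cat("Sweep plan:", nrow(x$cells), "runs (",
      length(unique(x$cells$phi)), "phi x",
      length(unique(x$cells$epsilon)), "epsilon x",
      x$n_replicates, "replicates ), profile", x$profile, "\n")
  invisible(x)
}

#' Desk-scale run template
#'
#' Default problem sizes for desk-scale sweeps: N = 300 monomers, 10
#' tracers, 3e5 steps per run with 1e5 equilibration steps and a snapshot
#' every 100 steps (2000 snapshots), box L = 50.
#'
#' @param N,n_tracers,L,dt,n_total,n_equil,sample_every,integrator Run
#'   parameters (see [simulation_config()]).
#' @return A list used as `template` by [run_sweep()].
#' @export
sweep_template <- function(N = 300, n_tracers = 10, L = 50, dt = 0.005,
                           n_total = 3e5, n_equil = 1e5,
                           sample_every = 100, integrator = "baoab") {
  list(N = N, n_tracers = n_tracers, L = L, dt = dt, n_total = n_total,
       n_equil = n_equil, sample_every = sample_every,
       integrator = integrator)
}

run_one_cell <- function(phi, epsilon, replicate, seed, template, t = 2) {
  topo <- build_topology(template$N, phi, seed = seed)
  cfg <- simulation_config(
    topo, epsilon = epsilon, n_tracers = template$n_tracers,
    L = template$L, dt = template$dt, n_total = template$n_total,
    n_equil = template$n_equil, sample_every = template$sample_every,
    seed = seed, integrator = template$integrator)
  traj <- run_simulation(cfg)
  cm <- contact_matrix(traj, t = t)
  tp <- traffic_profile(traj, t = t)
  cs <- correspondence(cm, tp)
  gd <- gyration_and_density(traj)
  data.frame(
    phi = phi, epsilon = epsilon, replicate = replicate, seed = seed,
    pearson_r = cs$pearson_r, d_kl = cs$d_kl, abs_d_kl = cs$abs_d_kl,
    coverage = coverage(tp),
    binder_exclusion_r = binder_exclusion(traj, t = t),
    bound_fraction = bound_fraction(traj, t = t),
    r_gyr = gd$r_gyr, rho_local = gd$rho_local)
}

#' Run a (phi, epsilon) sweep with replicates
#'
#' Executes one simulation per cell of the plan and returns the
#' per-replicate statistics (Pearson and KL correspondence, coverage,
#' binder exclusion, bound-time fraction, radius of gyration, local
#' density) plus a replicate-averaged grid. Grid averages are means over
#' replicates of per-replicate statistics, not statistics of pooled
#' profiles. When `outdir` is given each completed cell is written as a
#' one-row TSV, and an interrupted sweep resumes from the completed cells.
#'
#' @param plan A [sweep_plan()].
#' @param template A [sweep_template()].
#' @param outdir Optional directory for per-cell outputs / resumability.
#' @param resume Reuse completed cell files found in `outdir`
#'   (default `TRUE`).
#' @param verbose Print one line per cell.
#' @return List with `cells` (one row per run) and `grid` (replicate
#'   means keyed by phi and epsilon). Failed cells are recorded with NA
#'   statistics and the sweep continues.
#' @export
run_sweep <- function(plan, template = sweep_template(), outdir = NULL,
                      resume = TRUE, verbose = FALSE) {
  cells <- plan$cells
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cell <- cells[k, ]
    tag <- sprintf("cell_phi%s_eps%s_rep%d.tsv",
                   format(cell$phi, nsmall = 2),
                   format(cell$epsilon, nsmall = 1), cell$replicate)
    path <- if (!is.null(outdir)) file.path(outdir, tag) else NULL
    if (!is.null(path) && resume && file.exists(path)) {
      rows[[k]] <- read.table(path, header = TRUE, sep = "\t")
      next
    }
    row <- tryCatch(
      run_one_cell(cell$phi, cell$epsilon, cell$replicate, cell$seed,
                   template),
      error = function(e) {
        warning("cell (phi=", cell$phi, ", eps=", cell$epsilon, ", rep=",
                cell$replicate, ") failed: ", conditionMessage(e))
        data.frame(phi = cell$phi, epsilon = cell$epsilon,
                   replicate = cell$replicate, seed = cell$seed,
                   pearson_r = NA_real_, d_kl = NA_real_,
                   abs_d_kl = NA_real_, coverage = NA_real_,
                   binder_exclusion_r = NA_real_,
                   bound_fraction = NA_real_, r_gyr = NA_real_,
                   rho_local = NA_real_)
      })
    if (verbose) {
      message(sprintf("phi=%.2f eps=%.1f rep=%d: bound=%.1f%% r=%.2f",
                      cell$phi, cell$epsilon, cell$replicate,
                      row$bound_fraction, row$pearson_r))
    }
    if (!is.null(path)) {
      write.table(row, path, sep = "\t", row.names = FALSE, quote = FALSE)
    }
    rows[[k]] <- row
  }
  cells_out <- do.call(rbind, rows)
  stats <- setdiff(names(cells_out),
                   c("phi", "epsilon", "replicate", "seed"))
  grid <- aggregate(cells_out[stats],
                    by = cells_out[c("phi", "epsilon")],
                    FUN = mean, na.rm = TRUE)
  list(cells = cells_out, grid = grid)
}

#' Interpolate the affinity at a target bound-time fraction
#'
#' The bound-time fraction increases monotonically with the tracer
#' affinity; fixing it at a measured value (50\% for a factor that spends
#' half its time on chromatin, as reported for TetR) picks out the
#' corresponding epsilon by linear interpolation between the bracketing
#' grid points.
#'
#' @param sweep Either the result of [run_sweep()] or a data frame with
#'   columns `epsilon` and `bound_fraction` (replicates are averaged).
#' @param target Target bound-time percentage (default 50).
#' @return List with `epsilon` (the interpolated estimate), `bracket`
#'   (the two grid points used), `curve` (the replicate-mean curve) and
#'   `replicate_sd` per grid point.
#' @export
calibrate_epsilon <- function(sweep, target = 50) {
  df <- if (is.data.frame(sweep)) sweep else sweep$cells
  if (!all(c("epsilon", "bound_fraction") %in% names(df))) {
    stop("need columns 'epsilon' and 'bound_fraction'")
  }
  curve <- aggregate(bound_fraction ~ epsilon, df, mean)
  curve <- curve[order(curve$epsilon), ]
  spread <- aggregate(bound_fraction ~ epsilon, df, sd)
  if (nrow(curve) < 2) stop("need at least two epsilon values")
  if (any(diff(curve$bound_fraction) <= 0)) {
    warning("bound fraction is not strictly monotone over the sweep")
  }
  if (target < min(curve$bound_fraction) ||
      target > max(curve$bound_fraction)) {
    stop("target ", target, "% lies outside the observed range [",
         round(min(curve$bound_fraction), 1), ", ",
         round(max(curve$bound_fraction), 1), "]%")
  }
  ix <- max(which(curve$bound_fraction <= target))
  if (curve$bound_fraction[ix] == target) {
    eps_hat <- curve$epsilon[ix]
    bracket <- curve[ix, ]
  } else {
    x1 <- curve$bound_fraction[ix]
    x2 <- curve$bound_fraction[ix + 1]
    eps_hat <- curve$epsilon[ix] +
      (target - x1) / (x2 - x1) *
        (curve$epsilon[ix + 1] - curve$epsilon[ix])
    bracket <- curve[c(ix, ix + 1), ]
  }
  list(epsilon = eps_hat, bracket = bracket, curve = curve,
       replicate_sd = spread)
}
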