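# Heavy simulation campaigns shared between acceptance-level tests.
# Computed once per test session and cached; all seeds fixed up front.

.campaign_cache <- new.env(parent = emptyenv())

campaign_cached <- function(name, compute) {
  if (!exists(name, envir = .campaign_cache)) {
    assign(name, compute(), envir = .campaign_cache)
  }
  get(name, envir = .campaign_cache)
}

# affinity sweep at phi = 0.10: 10 epsilon values x 3 replicates
campaign_sweep <- function() {
  campaign_cached("sweep", function() {
    plan <- sweep_plan(0.10, epsilon_grid(), n_replicates = 3,
                      base_seed = 101)
    run_sweep(plan, sweep_template())
  })
}

# 2 x 2 extreme grid: phi in {0.02, 0.50} x epsilon in {0.9, 2.7},
# 3 replicates
campaign_grid <- function() {
  campaign_cached("grid", function() {
    plan <- sweep_plan(c(0.02, 0.50), c(0.9, 2.7), n_replicates = 3,
                      base_seed = 101)
    run_sweep(plan, sweep_template())
  })
}

# equilibrated polymer+binder scaffolds at both compaction extremes,
# plus hard-core and epsilon = 0.9 tracer runs over the frozen scaffolds
campaign_frozen <- function() {
  campaign_cached("frozen", function() {
    out <- list()
    for (p in c(0.02, 0.50)) {
      topo <- build_topology(300, p, seed = 131)
      cfg <- simulation_config(topo, epsilon = 1.0, n_tracers = 0,
                               n_total = 1e5, n_equil = 1e5 - 100,
                               sample_every = 100, seed = 131)
      st <- build_initial_state(cfg)
      eq <- equilibrate(st, cfg)
      tr_hard <- run_tracers_on_state(eq, topo, epsilon = 0,
                                      n_tracers = 10, seed = 201,
                                      n_total = 2e6, n_equil = 2e5,
                                      sample_every = 100)
      tr_weak <- run_tracers_on_state(eq, topo, epsilon = 0.9,
                                      n_tracers = 10, seed = 202,
                                      n_total = 2e6, n_equil = 2e5,
                                      sample_every = 100)
      key <- sprintf("phi%.2f", p)
      out[[key]] <- list(
        scaffold = eq,
        r_gyr = gyration_and_density(tr_hard)$r_gyr,
        traffic_cor = cor(traffic_profile(tr_hard)$C,
                          traffic_profile(tr_weak)$C))
    }
    out
  })
}
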