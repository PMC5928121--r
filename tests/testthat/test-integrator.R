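no_bonds <- matrix(integer(0), 0, 2)

test_that("free Brownian particles recover the Einstein diffusion law", {
  # 100 non-interacting particles; MSD over a lag tau must be 6 D tau
  n <- 100
  set.seed(3)
  pos <- matrix(runif(3 * n, 0, 100), n, 3)
  zt <- zero_table()
  res <- engine_raw(pos, rep(3L, n), no_bonds, zt$eps, zt$xi, L = 100,
                    dt = 0.01, gamma = 1, n_total = 20000, n_equil = 0,
                    sample_every = 100, seed = 91, scheme = "brownian")
  snaps <- res$snapshots
  S <- dim(snaps)[3]
  lag_t <- 100 * 0.01
  msd <- 0
  cnt <- 0
  for (s in 2:S) {
    d <- minimum_image(snaps[, , s - 1], snaps[, , s], 100)
    msd <- msd + sum(d^2)
    cnt <- cnt + n
  }
  D_hat <- (msd / cnt) / (6 * lag_t)
  expect_equal(D_hat, 1, tolerance = 0.05)  # D = kT / gamma = 1
})

test_that("BAOAB thermostats the kinetic temperature to kT", {
  n <- 100
  set.seed(4)
  pos <- matrix(runif(3 * n, 0, 100), n, 3)
  zt <- zero_table()
  res <- engine_raw(pos, rep(3L, n), no_bonds, zt$eps, zt$xi, L = 100,
                    dt = 0.005, gamma = 1, n_total = 20000, n_equil = 0,
                    sample_every = 20000, seed = 92, scheme = "baoab")
  temps <- res$diagnostics$kinetic_temp
  expect_equal(mean(temps), 1, tolerance = 0.05)
})

test_that("a stiff bond samples the equipartition variance", {
  # bonded pair, LJ off: var(r - r0) = kT / k = 1/330
  pos <- rbind(c(25, 25, 25), c(26.2, 25, 25))
  zt <- zero_table()
  res <- engine_raw(pos, c(0L, 0L), cbind(0L, 1L), zt$eps, zt$xi, L = 50,
                    dt = 0.005, gamma = 1, n_total = 2e5, n_equil = 1e4,
                    sample_every = 50, seed = 93, scheme = "baoab")
  snaps <- res$snapshots
  r <- sapply(seq_len(dim(snaps)[3]), function(s) {
    sqrt(sum(minimum_image(snaps[1, , s], snaps[2, , s], 50)^2))
  })
  expect_equal(var(r), 1 / 330, tolerance = 0.15)
  expect_equal(mean(r), 1.2, tolerance = 0.02)
})

test_that("frozen particles never move; all-frozen leaves state identical", {
  set.seed(5)
  pos <- matrix(runif(30, 0, 20), 10, 3)
  zt <- zero_table()
  res <- engine_raw(pos, rep(3L, 10), no_bonds, zt$eps, zt$xi, L = 20,
                    dt = 0.005, gamma = 1, n_total = 1000, n_equil = 0,
                    sample_every = 1000, seed = 94,
                    mobile = rep(FALSE, 10))
  expect_identical(res$final_positions[, 1], pos[, 1] %% 20)
  expect_identical(res$final_positions[, 2], pos[, 2] %% 20)
  expect_identical(res$final_positions[, 3], pos[, 3] %% 20)
})

test_that("runs are bit-reproducible from the seed", {
  topo <- build_topology(40, 0.1, seed = 6)
  cfg <- simulation_config(topo, epsilon = 1.5, n_tracers = 4,
                           n_total = 3000, n_equil = 1000,
                           sample_every = 100, seed = 17)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$coords, t2$coords)
  cfg2 <- cfg
  cfg2$seed <- 18L
  t3 <- run_simulation(cfg2)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("snapshot bookkeeping matches the sampling protocol", {
  topo <- build_topology(30, 0.1, seed = 7)
  cfg <- simulation_config(topo, epsilon = 1, n_tracers = 2,
                           n_total = 3000, n_equil = 1000,
                           sample_every = 100, seed = 19)
  traj <- run_simulation(cfg)
  expect_equal(n_snapshots(traj), (3000 - 1000) / 100)
  expect_equal(traj$steps[1], 1100)
  expect_equal(diff(traj$steps), rep(100, n_snapshots(traj) - 1))
  # the full-scale protocol arithmetic follows the same formula
  expect_equal((1e8 - 2e7) / 1e4, 8000)
})

test_that("deterministic BAOAB limit conserves energy", {
  # gamma = 0 reduces BAOAB to velocity Verlet; compare total energy
  # (potential + kinetic) after k and 2k steps of the same run
  set.seed(8)
  n <- 10
  # gently perturbed chain near the bond rest length
  pos <- cbind(25 + 1.25 * seq_len(n), 25, 25) +
    matrix(rnorm(3 * n, sd = 0.05), n, 3)
  bonds <- cbind(0:(n - 2), 1:(n - 1))
  tab <- make_interaction_table(0)
  energy_at <- function(steps) {
    res <- engine_raw(pos, rep(0L, n), bonds, tab$eps, tab$xi, L = 50,
                      dt = 0.002, gamma = 0, n_total = steps,
                      n_equil = 0, sample_every = steps, seed = 95,
                      scheme = "baoab")
    topo <- structure(
      list(N = n, phi = 0, anchor_indices = integer(0),
           bonds = bonds + 1L, seed = 0L),
      class = "polymer_topology")
    st <- sim_state(res$final_positions, rep("p", n), 50)
    pe <- total_energy(st, topo, tab)
    ke <- 0.5 * sum(res$final_velocities^2)
    pe + ke
  }
  e1 <- energy_at(5000)
  e2 <- energy_at(10000)
  expect_equal(e2, e1, tolerance = 1e-3)
})

test_that("bound-time fraction rises monotonically with affinity", {
  sweep <- campaign_sweep()
  curve <- aggregate(bound_fraction ~ epsilon, sweep$cells, mean)
  curve <- curve[order(curve$epsilon), ]
  se <- aggregate(bound_fraction ~ epsilon, sweep$cells,
                  function(x) sd(x) / sqrt(length(x)))
  se <- se[order(se$epsilon), ]
  # every step rises, up to replicate sampling error
  se_diff <- sqrt(head(se$bound_fraction, -1)^2 +
                    tail(se$bound_fraction, -1)^2)
  expect_true(all(diff(curve$bound_fraction) > -2 * se_diff))
  # and the overall trend across all replicate cells is monotone
  expect_gt(cor(sweep$cells$epsilon, sweep$cells$bound_fraction,
                method = "spearman"), 0.9)
})

test_that("strong bridging collapses the polymer; sparse anchors do not", {
  frozen <- campaign_frozen()
  rg_open <- frozen[["phi0.02"]]$r_gyr
  rg_compact <- frozen[["phi0.50"]]$r_gyr
  expect_gt(rg_open / rg_compact, 1.5)
})
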