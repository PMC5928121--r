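test_that("contact matrix follows the strict threshold rule", {
  frames <- list(rbind(c(10, 10, 10), c(11.5, 10, 10), c(20, 20, 20)))
  traj <- toy_trajectory(frames, c("p", "p", "p"), L = 50)
  H <- contact_matrix(traj, t = 2, exclude_window = 0)$H
  expect_equal(H[1, 2], 1)
  expect_equal(H[1, 3], 0)

  # 2.5 sigma apart: no contact
  frames2 <- list(rbind(c(10, 10, 10), c(12.5, 10, 10)))
  traj2 <- toy_trajectory(frames2, c("p", "p"), L = 50)
  expect_equal(contact_matrix(traj2, exclude_window = 0)$H[1, 2], 0)

  # periodic wrap: 0.5 and 49.0 are 1.5 sigma apart in L = 50
  frames3 <- list(rbind(c(0.5, 0, 0), c(49.0, 0, 0)))
  traj3 <- toy_trajectory(frames3, c("p", "p"), L = 50)
  expect_equal(contact_matrix(traj3, exclude_window = 0)$H[1, 2], 1)

  # ties at exactly t are excluded (strict comparison)
  frames4 <- list(rbind(c(10, 10, 10), c(12, 10, 10)))
  traj4 <- toy_trajectory(frames4, c("p", "p"), L = 50)
  expect_equal(contact_matrix(traj4, exclude_window = 0)$H[1, 2], 0)

  # bonded neighbors excluded by default
  frames5 <- list(rbind(c(10, 10, 10), c(11.2, 10, 10), c(10, 11, 10)))
  traj5 <- toy_trajectory(frames5, c("p", "p", "p"), L = 50)
  H5 <- contact_matrix(traj5)$H
  expect_equal(H5[1, 2], 0)  # bonded pair dropped
  expect_equal(H5[1, 3], 1)  # |i-j| = 2 at distance 1: kept
})

test_that("traffic counts tracer-monomer contacts over tracers and time", {
  # one tracer at 1.9 sigma from monomer 5 only
  mono <- cbind(seq(2, 20, by = 2), 10, 10)
  tracer1 <- c(mono[5, 1], 10 + 1.9, 10)
  frames <- list(rbind(mono, tracer1))
  traj <- toy_trajectory(frames, c(rep("p", 10), "t"), L = 50)
  tp <- traffic_profile(traj)
  expect_equal(tp$C[5], 1)
  expect_equal(sum(tp$C), 1)

  # two tracers within t of monomer 5: C_5 = 2
  tracer2 <- c(mono[5, 1], 10 - 1.9, 10)
  frames2 <- list(rbind(mono, tracer1, tracer2))
  traj2 <- toy_trajectory(frames2, c(rep("p", 10), "t", "t"), L = 50)
  expect_equal(traffic_profile(traj2)$C[5], 2)

  # binders are never counted as polymer
  frames3 <- list(rbind(mono, c(30, 30, 30), tracer1))
  traj3 <- toy_trajectory(frames3, c(rep("p", 10), "b", "t"), L = 50)
  expect_length(traffic_profile(traj3)$C, 10)

  expect_error(traffic_profile(toy_trajectory(
    list(mono), rep("p", 10), 50)), "no 't'")
})

test_that("contact and traffic computations equal the brute force", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(15:40, 1)
    nt <- sample(2:5, 1)
    S <- sample(1:4, 1)
    L <- 12
    species <- c(rep("p", n), rep("t", nt))
    frames <- lapply(seq_len(S), function(s) {
      matrix(runif(3 * (n + nt), 0, L), n + nt, 3)
    })
    traj <- toy_trajectory(frames, species, L)
    coords <- traj$coords
    H <- contact_matrix(traj, t = 2)$H
    expect_identical(H, oracle_contact_matrix(coords, 1:n, L, 2, 1))
    tp <- traffic_profile(traj, t = 2)
    want <- oracle_cross(coords, n + seq_len(nt), 1:n, L, 2)
    expect_identical(tp$C, colSums(want$counts))
    expect_identical(as.integer(tp$bound_obs), want$bound)
  }
})

test_that("KL divergence matches direct evaluation of its formula", {
  expect_equal(kl_divergence(c(3, 5, 2), c(3, 5, 2)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(0.5) + 0.5 * log(1.5), tolerance = 1e-12)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(0.5),
               tolerance = 1e-12)
  # always <= 0 over random count profiles
  set.seed(41)
  for (i in 1:25) {
    C <- rpois(30, 5)
    R <- rpois(30, 5)
    if (sum(C) == 0 || sum(R) == 0) next
    expect_lte(kl_divergence(C, R), 1e-12)
  }
  expect_error(kl_divergence(c(0, 0), c(1, 1)), "all-zero")
  expect_error(kl_divergence(1:3, 1:4), "length")
})

test_that("correspondence is scale-invariant and sign-faithful", {
  cm <- list(row_sum = c(2, 4, 6, 8, 10), t = 2, n_snapshots = 1)
  class(cm) <- "polymer_contacts"
  tp <- list(C = 2 * c(2, 4, 6, 8, 10))
  class(tp) <- "traffic_profile"
  cs <- correspondence(cm, tp)
  expect_equal(cs$pearson_r, 1)
  expect_equal(cs$d_kl, 0, tolerance = 1e-12)

  tp_rev <- list(C = rev(c(2, 4, 6, 8, 10)))
  class(tp_rev) <- "traffic_profile"
  expect_lt(correspondence(cm, tp_rev)$pearson_r, 0)

  # matches the textbook two-pass formula on random profiles
  set.seed(43)
  for (i in 1:10) {
    R <- rpois(20, 8) + 1
    C <- rpois(20, 8) + 1
    cmx <- list(row_sum = R)
    class(cmx) <- "polymer_contacts"
    tpx <- list(C = C)
    class(tpx) <- "traffic_profile"
    expect_equal(correspondence(cmx, tpx)$pearson_r, oracle_pearson(C, R),
                 tolerance = 1e-12)
  }

  # zero variance: undefined, not zero
  cm0 <- list(row_sum = rep(3, 5))
  class(cm0) <- "polymer_contacts"
  expect_true(is.na(correspondence(cm0, tp)$pearson_r))
})

test_that("coverage is the percentage of visited monomers", {
  tp <- list(C = c(1, 2, 3))
  class(tp) <- "traffic_profile"
  expect_equal(coverage(tp), 100)
  tp$C <- rep(0, 4)
  expect_equal(coverage(tp), 0)
  tp$C <- c(1, 1, 0, 0, 0, 0, 2, 5, 0, 0)
  expect_equal(coverage(tp), 40)
})

test_that("binder exclusion correlates tracer and binder occupancy", {
  # tracers on monomers 1-5, binders on monomers 6-10: disjoint -> negative
  mono <- cbind(seq(0, 45, by = 5), 25, 25)
  tracers <- cbind(seq(0, 20, by = 5), 25 + 1.5, 25)
  binders <- cbind(seq(25, 45, by = 5), 25 - 1.5, 25)
  frames <- list(rbind(mono, binders, tracers))
  traj <- toy_trajectory(frames, c(rep("p", 10), rep("b", 5), rep("t", 5)),
                         L = 50)
  r <- binder_exclusion(traj)
  expect_lt(r, 0)
  # identical occupancy: r = 1
  frames2 <- list(rbind(mono, tracers, tracers))
  traj2 <- toy_trajectory(frames2, c(rep("p", 10), rep("b", 5),
                                     rep("t", 5)), L = 50)
  expect_equal(binder_exclusion(traj2), 1)
  # equals a brute-force recomputation
  set.seed(44)
  frames3 <- list(matrix(runif(60, 0, 12), 20, 3),
                  matrix(runif(60, 0, 12), 20, 3))
  sp3 <- c(rep("p", 12), rep("b", 4), rep("t", 4))
  traj3 <- toy_trajectory(frames3, sp3, L = 12)
  tcnt <- oracle_cross(traj3$coords, 17:20, 1:12, 12, 2)
  bcnt <- oracle_cross(traj3$coords, 13:16, 1:12, 12, 2)
  expect_equal(binder_exclusion(traj3),
               oracle_pearson(colSums(tcnt$counts), colSums(bcnt$counts)),
               tolerance = 1e-12)
})

test_that("gyration radius and local density follow their formulas", {
  # 3-monomer rod at unit spacing: r_gyr = sqrt(2/3)
  rod <- rbind(c(24, 25, 25), c(25, 25, 25), c(26, 25, 25))
  traj <- toy_trajectory(list(rod), c("p", "p", "p"), L = 50)
  gd <- gyration_and_density(traj)
  expect_equal(gd$r_gyr, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(gd$rho_local, 3 / sqrt(2 / 3)^3, tolerance = 1e-12)

  # rho = N (sigma / r_gyr)^3 arithmetic: N = 100, r_gyr = 10 -> 0.1
  expect_equal(100 * (1 / 10)^3, 0.1)

  # unwrapping: a chain laid across the periodic boundary keeps its size
  chain <- cbind(seq(48, 54, by = 1.2) %% 50, 25, 25)
  trajw <- toy_trajectory(list(chain), rep("p", nrow(chain)), L = 50)
  ref <- cbind(seq(48, 54, by = 1.2), 25, 25)
  rg_ref <- sqrt(mean(rowSums(sweep(ref, 2, colMeans(ref))^2)))
  expect_equal(gyration_and_density(trajw)$r_gyr, rg_ref,
               tolerance = 1e-12)
})

test_that("bound fraction is the share of bound tracer observations", {
  mono <- cbind(seq(2, 20, by = 2), 10, 10)
  near <- c(10, 11.5, 10)
  far <- c(40, 40, 40)
  sp <- c(rep("p", 10), "t")
  # bound in every snapshot
  traj <- toy_trajectory(list(rbind(mono, near), rbind(mono, near)), sp, 50)
  expect_equal(bound_fraction(traj), 100)
  # never bound
  traj0 <- toy_trajectory(list(rbind(mono, far), rbind(mono, far)), sp, 50)
  expect_equal(bound_fraction(traj0), 0)
  # 3 of 4 observations bound
  sp2 <- c(rep("p", 10), "t", "t")
  trajm <- toy_trajectory(list(rbind(mono, near, near),
                               rbind(mono, near, far)), sp2, 50)
  expect_equal(bound_fraction(trajm), 75)
})

test_that("profiles and matrices export to the documented text formats", {
  frames <- list(rbind(c(10, 10, 10), c(11.5, 10, 10), c(10, 11.5, 10),
                       c(10.5, 10.5, 11)))
  traj <- toy_trajectory(frames, c("p", "p", "p", "t"), L = 50)
  cm <- contact_matrix(traj)
  dense <- withr::local_tempfile(fileext = ".tsv")
  sparse <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(cm, dense, "dense")
  write_contact_matrix(cm, sparse, "sparse")
  expect_equal(unname(as.matrix(read.table(dense))), unname(cm$H))
  sp <- read.table(sparse, header = TRUE)
  expect_true(all(cm$H[cbind(sp$i, sp$j)] == sp$count))
  prof <- withr::local_tempfile(fileext = ".tsv")
  tp <- traffic_profile(traj)
  write_profile(tp, prof)
  got <- read.table(prof, header = TRUE)
  expect_equal(got$count, as.vector(tp$C))
})
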