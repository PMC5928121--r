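#' Intra-polymer boolean contact matrix summed over snapshots
#'
#' For every snapshot, two monomers are in contact when their minimum-image
#' center-to-center distance is strictly below the threshold `t` (default
#' 2 sigma, the particle diameter, a distance at which the Lennard-Jones
#' interaction is practically zero). Each snapshot contributes 0 or 1 per
#' pair; the matrix `H` sums these booleans. Bonded neighbors
#' (`|i - j| <= 1`) are excluded since they are trivially always in
#' contact. The row sums `R_i` are the per-monomer "polymer contacts", the
#' simulation analogue of a Hi-C row sum.
#'
#' @param traj A `sim_trajectory`.
#' @param t Contact threshold in sigma (default 2).
#' @param exclude_window Chain-separation window excluded from `H`
#'   (default 1: self and bonded neighbors).
#' @return An object of class `polymer_contacts`: list with `H` (N x N),
#'   `row_sum`, `t`, `n_snapshots`.
#' @export
contact_matrix <- function(traj, t = 2, exclude_window = 1L) {
  if (t <= 0) stop("'t' must be positive")
  if (n_snapshots(traj) < 1) stop("trajectory has no snapshots")
  idx <- which(traj$species %in% c("p", "a"))
  H <- .contact_hist_cpp(traj$coords, idx, traj$box_edge, t,
                         as.integer(exclude_window))
  structure(list(H = H, row_sum = rowSums(H), t = t,
                 n_snapshots = n_snapshots(traj)),
            class = "polymer_contacts")
}

#' @export
print.polymer_contacts <- function(x, ...) {
  cat("Polymer contact matrix:", nrow(x$H), "monomers,",
      x$n_snapshots, "snapshots, threshold", x$t, "sigma\n")
  invisible(x)
}

#' Tracer traffic profile
#'
#' Counts, for each monomer (both `p` and `a`; binders excluded), the
#' number of (tracer, snapshot) pairs whose minimum-image distance falls
#' strictly below `t`. Summing over all tracers and snapshots gives the
#' total time tracers spent in contact with each region of the polymer.
#'
#' @inheritParams contact_matrix
#' @return An object of class `traffic_profile`: list with `C` (per-monomer
#'   counts), `n_snapshots`, `n_tracers`, `bound_obs` (number of
#'   (tracer, snapshot) observations with at least one monomer contact).
#' @export
traffic_profile <- function(traj, t = 2) {
  occupancy_profile(traj, species = "t", t = t)
}

#' Occupancy profile of a diffusible species
#'
#' Same contact rule as [traffic_profile()] but for an arbitrary mobile
#' species; `species = "b"` gives the binder occupancy.
#'
#' @inheritParams contact_matrix
#' @param species Species whose contacts with the polymer are counted
#'   (`"t"` or `"b"`).
#' @return A `traffic_profile` object.
#' @export
occupancy_profile <- function(traj, species = c("t", "b"), t = 2) {
  species <- match.arg(species)
  if (t <= 0) stop("'t' must be positive")
  idx_m <- which(traj$species %in% c("p", "a"))
  idx_s <- which(traj$species == species)
  if (!length(idx_s)) {
    stop("trajectory contains no '", species, "' particles")
  }
  res <- .cross_contacts_cpp(traj$coords, idx_s, idx_m, traj$box_edge, t)
  structure(list(C = colSums(res$counts), species = species,
                 counts = res$counts,
                 n_snapshots = n_snapshots(traj),
                 n_tracers = length(idx_s),
                 bound_obs = res$bound_obs, n_obs = res$n_obs, t = t),
            class = "traffic_profile")
}

#' @export
print.traffic_profile <- function(x, ...) {
  cat("Occupancy profile (", x$species, "):", length(x$C), "monomers,",
      x$n_tracers, "particles x", x$n_snapshots, "snapshots; total contacts",
      sum(x$C), "\n")
  invisible(x)
}

#' Kullback-Leibler correspondence of two profiles
#'
#' \deqn{D_{KL}(C|R) = \sum_i C_i \log(R_i / C_i)} with both profiles
#' normalized to unit sum and interpreted as probability distributions
#' (natural log). Terms with \eqn{C_i = 0} contribute zero. In this
#' orientation the value is \eqn{\le 0}, and 0 exactly when the normalized
#' profiles coincide on the support of `C`; small magnitudes mean high
#' correspondence. Zero entries of `R` facing a positive `C` receive one
#' pseudo-count before normalization to keep the sum finite.
#'
#' @param C,R Non-negative count-like vectors of equal length (tracer
#'   traffic and polymer contacts).
#' @return Scalar divergence (<= 0).
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))  # ~ -0.1438
#' @export
kl_divergence <- function(C, R) {
  if (length(C) != length(R)) stop("'C' and 'R' must have equal length")
  if (any(C < 0) || any(R < 0)) stop("profiles must be non-negative")
  if (sum(C) == 0 || sum(R) == 0) stop("all-zero profile")
  R <- ifelse(R == 0 & C > 0, 1, R)
  p <- C / sum(C)
  q <- R / sum(R)
  s <- p > 0
  sum(p[s] * log(q[s] / p[s]))
}

#' Correspondence between polymer contacts and tracer traffic
#'
#' Pearson correlation on the raw per-monomer counts plus the
#' Kullback-Leibler divergence of the normalized profiles. A
#' zero-variance input leaves the correlation undefined (`NA`), not 0.
#'
#' @param cm A [contact_matrix()] result.
#' @param tp A [traffic_profile()] result on the same monomer indexing.
#' @return An object of class `correspondence_stats`: list with
#'   `pearson_r`, `d_kl` (Eq.-oriented, <= 0) and `abs_d_kl`.
#' @export
correspondence <- function(cm, tp) {
  R <- cm$row_sum
  C <- tp$C
  if (length(R) != length(C)) {
    stop("contact matrix and traffic profile cover different monomer sets")
  }
  r <- if (sd(R) == 0 || sd(C) == 0) NA_real_ else cor(C, R)
  d <- if (sum(C) == 0 || sum(R) == 0) NA_real_ else kl_divergence(C, R)
  structure(list(pearson_r = r, d_kl = d, abs_d_kl = abs(d)),
            class = "correspondence_stats")
}

#' @export
print.correspondence_stats <- function(x, ...) {
  cat("Correspondence: Pearson r =", round(x$pearson_r, 3),
      "; D_KL =", signif(x$d_kl, 4), "\n")
  invisible(x)
}

#' Tracer coverage of the polymer
#'
#' Percentage of monomers visited by at least one tracer during the run.
#'
#' @param tp A [traffic_profile()].
#' @return Percentage in [0, 100].
#' @export
coverage <- function(tp) {
  100 * sum(tp$C > 0) / length(tp$C)
}

#' Tracer-binder occupancy correlation
#'
#' Computes the binder occupancy profile (same contact rule and threshold
#' as the tracer traffic) and returns its Pearson correlation with the
#' tracer traffic. Strongly negative values mean binders exclude tracers
#' from the looping sites.
#'
#' @inheritParams contact_matrix
#' @return Scalar correlation (NA if either profile has zero variance).
#' @export
binder_exclusion <- function(traj, t = 2) {
  tp <- traffic_profile(traj, t = t)
  bp <- occupancy_profile(traj, species = "b", t = t)
  if (sd(tp$C) == 0 || sd(bp$C) == 0) return(NA_real_)
  cor(tp$C, bp$C)
}

#' Radius of gyration and local density
#'
#' The polymer radius of gyration is computed per snapshot on unwrapped
#' coordinates (reconstructed by walking the chain with minimum-image
#' steps, since wrapped coordinates corrupt the estimate), then averaged.
#' The local density follows \eqn{\rho_{local} = N (\sigma / r_{gyr})^3}.
#'
#' @param traj A `sim_trajectory`.
#' @return List with `r_gyr` (snapshot mean), `rho_local` and
#'   `r_gyr_series`.
#' @export
gyration_and_density <- function(traj) {
  N <- traj$config$topology$N
  rg <- .rg_series_cpp(traj$coords, seq_len(N), traj$box_edge)
  r_gyr <- mean(rg)
  list(r_gyr = r_gyr, rho_local = N * (1 / r_gyr)^3, r_gyr_series = rg)
}

#' Bound-time fraction of the tracers
#'
#' Percentage of (tracer, snapshot) observations in which the tracer is
#' within `t` of at least one monomer - the share of simulation time the
#' tracers spend bound to the polymer.
#'
#' @inheritParams contact_matrix
#' @return Percentage in [0, 100].
#' @export
bound_fraction <- function(traj, t = 2) {
  tp <- traffic_profile(traj, t = t)
  100 * tp$bound_obs / tp$n_obs
}

#' Export a contact matrix as text
#'
#' @param cm A [contact_matrix()] result.
#' @param path Output path.
#' @param format `"dense"` (tab-separated matrix) or `"sparse"`
#'   (three columns i, j, count, upper triangle only).
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  if (format == "dense") {
    write.table(cm$H, path, sep = "\t", row.names = FALSE,
                col.names = FALSE)
  } else {
    idx <- which(upper.tri(cm$H) & cm$H > 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1], j = idx[, 2], count = cm$H[idx])
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export a per-monomer profile as two-column TSV
#'
#' @param tp A [traffic_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(tp, path) {
  write.table(data.frame(monomer_index = seq_along(tp$C), count = tp$C),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
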