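# Independent brute-force oracles, written without reference to the
# package internals they validate.

oracle_min_image <- function(d, L) d - L * round(d / L)

oracle_dist <- function(p1, p2, L) {
  sqrt(sum(oracle_min_image(p1 - p2, L)^2))
}

# all-pairs boolean contact matrix summed over snapshots (strict < t)
oracle_contact_matrix <- function(coords, idx, L, t, exclude_window = 1) {
  K <- length(idx)
  S <- dim(coords)[3]
  H <- matrix(0L, K, K)
  for (s in seq_len(S)) {
    for (a in seq_len(K - 1)) {
      for (b in (a + 1):K) {
        if (b - a <= exclude_window) next
        if (oracle_dist(coords[idx[a], , s], coords[idx[b], , s], L) < t) {
          H[a, b] <- H[a, b] + 1L
          H[b, a] <- H[b, a] + 1L
        }
      }
    }
  }
  H
}

# tracer x monomer contact counts and bound observations
oracle_cross <- function(coords, idxA, idxB, L, t) {
  S <- dim(coords)[3]
  counts <- matrix(0L, length(idxA), length(idxB))
  bound <- 0L
  for (s in seq_len(S)) {
    for (a in seq_along(idxA)) {
      hit <- FALSE
      for (b in seq_along(idxB)) {
        if (oracle_dist(coords[idxA[a], , s], coords[idxB[b], , s], L) < t) {
          counts[a, b] <- counts[a, b] + 1L
          hit <- TRUE
        }
      }
      if (hit) bound <- bound + 1L
    }
  }
  list(counts = counts, bound = bound)
}

oracle_pairs <- function(pos, L, cutoff) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (oracle_dist(pos[i, ], pos[j, ], L) < cutoff) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Welch two-sample statistic, Welch-Satterthwaite df
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df)
}

# assemble a hand-placed trajectory object for analysis tests
toy_trajectory <- function(frames, species, L) {
  n <- nrow(frames[[1]])
  coords <- array(NA_real_, c(n, 3, length(frames)))
  for (s in seq_along(frames)) coords[, , s] <- frames[[s]] %% L
  N <- sum(species %in% c("p", "a"))
  topo <- structure(
    list(N = N, phi = 0,
         anchor_indices = which(species == "a"),
         bonds = if (N > 1) cbind(seq_len(N - 1), seq_len(N - 1) + 1)
                 else matrix(integer(0), 0, 2),
         seed = 0L),
    class = "polymer_topology")
  structure(
    list(coords = coords, species = species, box_edge = L,
         steps = seq_along(frames), config = list(topology = topo),
         fixed_polymer = TRUE, diagnostics = NULL,
         final_state = NULL,
         provenance = list(package = "chromotracer", version = "0",
                           seed = 0L)),
    class = "sim_trajectory")
}

# direct access to the compiled engine for scheme-level checks
engine_raw <- function(pos, species_codes, bonds, eps, xi, L, dt, gamma,
                       n_total, n_equil, sample_every, seed,
                       scheme = "baoab", mobile = NULL, kT = 1,
                       rcut = 3, kbond = 330, r0 = 1.2) {
  if (is.null(mobile)) mobile <- rep(TRUE, nrow(pos))
  chromotracer:::.run_engine_cpp(
    pos, species_codes, bonds, eps, xi, L, rcut, kbond, r0, dt, gamma,
    kT, n_total, n_equil, sample_every, mobile, 0.4, seed, scheme,
    0, if (scheme == "brownian") 0.3 else 0,
    integer(0), 1000L)
}

zero_table <- function() {
  list(eps = matrix(0, 4, 4), xi = matrix(0, 4, 4))
}
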