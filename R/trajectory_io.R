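#' Write a trajectory archive
#'
#' The native archive is plain text: a self-describing JSON header line
#' followed by extended-XYZ frames (one species label and three `%.17g`
#' coordinates per particle, with the box edge and step index on each
#' frame's comment line). Full-precision coordinates round-trip
#' bit-exactly, and an interrupted write leaves a readable prefix that
#' [read_trajectory()] flags as truncated.
#'
#' @param traj A `sim_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cfg <- traj$config
  header <- list(
    format = "chromotracer-trajectory",
    version = 1L,
    package_version = traj$provenance$version,
    seed = traj$provenance$seed,
    n_particles = length(traj$species),
    n_snapshots = n_snapshots(traj),
    box_edge = traj$box_edge,
    fixed_polymer = isTRUE(traj$fixed_polymer),
    config = list(
      N = cfg$topology$N, phi = cfg$topology$phi,
      anchor_indices = cfg$topology$anchor_indices,
      topology_seed = cfg$topology$seed,
      epsilon = cfg$epsilon, n_tracers = cfg$n_tracers,
      n_binders = cfg$n_binders, L = cfg$L, dt = cfg$dt,
      gamma = cfg$gamma, kT = cfg$kT, n_total = cfg$n_total,
      n_equil = cfg$n_equil, sample_every = cfg$sample_every,
      seed = cfg$seed, integrator = cfg$integrator))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#chromotracer ",
                    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)),
             con)
  n <- length(traj$species)
  S <- n_snapshots(traj)
  for (s in seq_len(S)) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3 step=%d',
      traj$box_edge, traj$box_edge, traj$box_edge, traj$steps[s]), con)
    writeLines(sprintf("%s %.17g %.17g %.17g", traj$species,
                       traj$coords[, 1, s], traj$coords[, 2, s],
                       traj$coords[, 3, s]), con)
  }
  invisible(path)
}

#' Read a trajectory archive
#'
#' @param path Path written by [write_trajectory()].
#' @return A `sim_trajectory`. If the file ends mid-frame the complete
#'   prefix is returned with attribute `"truncated" = TRUE`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "#chromotracer ")) {
    stop("not a chromotracer trajectory archive: missing header line")
  }
  header <- jsonlite::fromJSON(sub("^#chromotracer ", "", lines[1]))
  if (!identical(header$format, "chromotracer-trajectory")) {
    stop("malformed archive header: unexpected format field")
  }
  n <- header$n_particles
  L <- header$box_edge
  cursor <- 2L
  frames <- list()
  steps <- integer(0)
  species <- NULL
  truncated <- FALSE
  while (cursor <= length(lines)) {
    if (nzchar(lines[cursor]) == FALSE) {
      cursor <- cursor + 1L
      next
    }
    if (cursor + 1L + n > length(lines)) {
      truncated <- TRUE
      break
    }
    n_here <- suppressWarnings(as.integer(lines[cursor]))
    if (is.na(n_here) || n_here != n) {
      stop("malformed archive at line ", cursor,
           ": expected particle count ", n)
    }
    comment <- lines[cursor + 1L]
    step <- suppressWarnings(as.integer(sub(".*step=(\\d+).*", "\\1",
                                            comment)))
    block <- lines[cursor + 1L + seq_len(n)]
    parts <- strsplit(block, " ", fixed = TRUE)
    if (any(lengths(parts) != 4L)) {
      bad <- which(lengths(parts) != 4L)[1]
      stop("malformed record at line ", cursor + 1L + bad)
    }
    sp <- vapply(parts, `[[`, "", 1L)
    species_code(sp)  # errors on labels outside {p,a,b,t}
    if (is.null(species)) {
      species <- sp
    } else if (!identical(sp, species)) {
      stop("species labels change between frames at line ", cursor)
    }
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), n, 3,
                  byrow = TRUE)
    frames[[length(frames) + 1L]] <- xyz
    steps <- c(steps, step)
    cursor <- cursor + 2L + n
  }
  S <- length(frames)
  coords <- array(NA_real_, c(n, 3, S))
  for (s in seq_len(S)) coords[, , s] <- frames[[s]]

  hc <- header$config
  topo <- structure(
    list(N = as.integer(hc$N), phi = hc$phi,
         anchor_indices = as.integer(hc$anchor_indices),
         bonds = cbind(seq_len(hc$N - 1L), seq_len(hc$N - 1L) + 1L),
         seed = as.integer(hc$topology_seed %||% hc$seed)),
    class = "polymer_topology")
  cfg <- simulation_config(
    topo, epsilon = hc$epsilon, n_tracers = hc$n_tracers, L = hc$L,
    dt = hc$dt, gamma = hc$gamma, kT = hc$kT, n_total = hc$n_total,
    n_equil = hc$n_equil, sample_every = hc$sample_every, seed = hc$seed,
    integrator = hc$integrator)
  traj <- structure(
    list(coords = coords, species = species, box_edge = L,
         steps = steps, config = cfg,
         fixed_polymer = isTRUE(header$fixed_polymer),
         diagnostics = NULL,
         final_state = if (S > 0) sim_state(coords[, , S], species, L)
                       else NULL,
         provenance = list(package = "chromotracer",
                           version = header$package_version,
                           seed = header$seed)),
    class = "sim_trajectory")
  attr(traj, "truncated") <- truncated
  traj
}

#' Export one snapshot as plain extended XYZ
#'
#' A single frame readable by standard molecular viewers (species label and
#' coordinates per line; box edge on the comment line).
#'
#' @param traj A `sim_trajectory`.
#' @param path Output path.
#' @param snapshot Snapshot index (default 1).
#' @return `path`, invisibly.
#' @export
export_xyz <- function(traj, path, snapshot = 1L) {
  if (snapshot < 1 || snapshot > n_snapshots(traj)) {
    stop("snapshot index out of range")
  }
  n <- length(traj$species)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(sprintf(
    'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3',
    traj$box_edge, traj$box_edge, traj$box_edge), con)
  writeLines(sprintf("%s %.8f %.8f %.8f", traj$species,
                     traj$coords[, 1, snapshot], traj$coords[, 2, snapshot],
                     traj$coords[, 3, snapshot]), con)
  invisible(path)
}
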