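Package: chromotracer
Title: Tracer Diffusion and Traffic on Folded Chromatin Polymers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained molecular dynamics of transcription-factor-like
    tracer particles diffusing on a strings-and-binders chromatin polymer.
    Provides a Langevin (BAOAB and Brownian) integrator over harmonic
    bead-spring bonds and truncated Lennard-Jones pair potentials in a cubic
    periodic box, builders for looped-polymer systems with diffusible binders
    and tracers, trajectory archives, and the trajectory statistics that link
    polymer conformation to tracer traffic: boolean contact matrices, tracer
    traffic and binder occupancy profiles, Pearson and Kullback-Leibler
    correspondence, coverage, bound-time fractions, radius of gyration and
    local density. A companion genomic stage estimates local Hi-C contact-decay
    exponents by windowed log-log regression, tests interval-set enrichment at
    chromatin loops under a binomial null, and generates synthetic contact
    matrices and interval sets with known truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
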