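# chromotracer

Coarse-grained molecular dynamics of transcription-factor-like **tracers**
diffusing on a folded **strings-and-binders** chromatin polymer, plus the
statistics that connect polymer conformation to tracer traffic, and a
genomic stage for Hi-C contact-decay and loop-enrichment analysis.

## The scientific problem

Transcription factors find most of their genomic targets while diffusing
in "search mode", hopping on and off chromatin through non-specific
affinity. Where the chromatin fiber folds back on itself — at the anchors
of chromosome loops — a searching factor can fall off one fiber and
reattach to the adjacent one, so genome conformation shapes the traffic
of searching proteins. This package implements a minimal physical model
of that process for people studying facilitated diffusion, chromosome
conformation, or promiscuous binding hot spots (HOTs):

- chromatin = a bead-spring homopolymer of `N` monomers (diameter σ,
  `k = 330 kT/σ²`, `r₀ = 1.2σ`), with a fraction φ of **anchor**
  monomers;
- **binders** (2 per anchor) attract anchors with a fixed deep well of
  `10 kT` and bridge them into stable loops — φ controls compaction;
- **tracers** carry a uniform non-specific affinity ε for the whole
  polymer and model factors in search mode;
- all pairs interact via a truncated Lennard-Jones potential
  `E(r) = 4ε_ij[(σ/r)¹² − ξ_ij(σ/r)⁶]`, cut off at `3σ`, in a periodic
  box of edge `50σ`, integrated with Langevin (BAOAB) dynamics at
  `kT = 1`, `γ = 1`.

From trajectories the package computes the boolean **contact matrix**
(threshold `t = 2σ`) and its row sums (the Hi-C-like "polymer
contacts" `R`), the **tracer traffic** `C`, their Pearson and
Kullback-Leibler correspondence `D_KL(C|R) = Σᵢ Cᵢ log(Rᵢ/Cᵢ)`,
tracer **coverage**, **binder exclusion**, **bound-time fraction**,
radius of gyration and local density `ρ = N(σ/r_gyr)³`. The genomic
stage estimates local contact-decay exponents α (contact probability
∝ s^−α) by windowed log-log regression and tests interval enrichment at
loops under a binomial null, with synthetic generators for both.

## A worked example

```r
library(chromotracer)

topo <- build_topology(N = 300, phi = 0.02, seed = 11)   # 6 anchors
cfg  <- simulation_config(topo, epsilon = 2.7, n_tracers = 10,
                          n_total = 3e5, n_equil = 1e5,
                          sample_every = 100, seed = 11)
traj <- run_simulation(cfg)          # ~10 s

cm <- contact_matrix(traj)           # intra-polymer contacts at t = 2σ
tp <- traffic_profile(traj)          # tracer-monomer contact counts
correspondence(cm, tp)
#> Correspondence: Pearson r = 0.786 ; D_KL = -0.2018
bound_fraction(traj)
#> [1] 81.5
coverage(tp)
#> [1] 99.66667
```

An open polymer (φ = 0.02) with sticky tracers (ε = 2.7 kT): the contact
row sums predict where tracers spend their time (r ≈ 0.8), tracers are
bound >80% of the time and have visited nearly every monomer. Repeating
at φ = 0.50, ε = 0.9 flips the picture (r < 0, coverage ≈ 13%): the
collapsed globule admits tracers only at its surface, where monomers
make the fewest contacts. `run_sweep(sweep_plan(...), sweep_template())`
runs whole (φ, ε) grids with replicates and resumable per-cell outputs,
and `calibrate_epsilon()` interpolates the affinity at a target
bound-time fraction (50% — the measured chromatin/nucleoplasm
partitioning of TetR — lands near ε ≈ 2 kT).

For the genomic stage:

```r
sh   <- synth_hic(n_bins = 200, alpha_background = -1.22,
                  noise_sdlog = 0.1, seed = 1)
prof <- contact_decay(sh$bins)            # per-50kb-window decay exponent
si   <- synth_intervals(n_hots = 2000, n_loops = 150,
                        genome_sizes = c(chr1 = 2e8, chr2 = 1e8),
                        enrichment_rho = 4, seed = 1)
hot_loop_enrichment(si$hots, si$loops, c(chr1 = 2e8, chr2 = 1e8))
#> Loop enrichment: 784 of 2000 intervals in loops vs 189.4 expected
#> (binomial P = 7.4e-276 )
```

`read_intervals()` ingests BED, Arrowhead domain/loop lists and
FASTA-header locus strings; `decay_at_intervals()` compares decay at
query intervals against the genome-wide set with a Welch t test. A thin
command-line front end with `simulate`, `sweep`, `calibrate-epsilon`,
`hic-decay`, `hot-enrichment` and `synth` subcommands is installed at
`inst/cli/chromotracer`.

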