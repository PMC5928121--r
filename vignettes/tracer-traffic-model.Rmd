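---
title: "Tracer traffic on folded chromatin polymers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer traffic on folded chromatin polymers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`chromotracer` simulates the search phase of transcription factors on a
folded chromatin fiber using a deliberately minimal coarse-grained
representation. Chromatin is a bead-spring homopolymer of `N` monomers of
diameter $\sigma$ (physically about 15 nm, the width of a thick chromatin
fiber; internally $\sigma = 1$ and $k_BT = 1$ fix the units). A fraction
$\phi$ of monomers are *anchors* (`a` particles); diffusible *binders*
(`b` particles, two per anchor, $n_b = 2\phi N$) attract anchors with a
fixed deep well of $10\,k_BT$ and bridge them into stable loops — the
strings-and-binders mechanism of chromosome folding. $\phi$ is the
compaction dial: at $\phi = 0.02$ the chain stays an open coil with a few
loops, at $\phi = 0.50$ it collapses into a globule. *Tracers*
(`t` particles) model transcription factors in search mode: they carry a
uniform, non-specific affinity $\varepsilon \equiv \varepsilon_{tp} =
\varepsilon_{ta}$ for every monomer and no affinity for any particular
site. Binders and tracers interact only by hard-core repulsion.

Bonded neighbors interact through harmonic springs,
$E = \tfrac{1}{2} k (|\mathbf r_{i+1} - \mathbf r_i| - r_0)^2$ with
$k = 330\,k_BT/\sigma^2$ and $r_0 = 1.2\sigma$. Every particle pair
additionally interacts through a truncated Lennard-Jones potential

$$E_{ij}(r) = 4\varepsilon_{ij}\left[(\sigma/r)^{12} -
\xi_{ij}(\sigma/r)^6\right], \qquad r < r_\mathrm{cut} = 3\sigma,$$

where $\xi_{ij}\in\{0,1\}$ switches the attractive tail on or off per
species pair. The potential is truncated without shifting; the
discontinuity at the cutoff, $4\varepsilon(3^{-12}-\xi\,3^{-6})$, is at
most $\sim0.015\,k_BT$ for the strongest pair and does not affect
equilibrium sampling at the contact threshold used throughout (an
energy-shift flag exists for sensitivity checks). The system lives in a
cubic box of edge $L = 50\sigma$ with periodic boundary conditions.

## Integration scheme

The dynamics is Langevin at constant temperature with drag $\gamma = 1$
per particle. The default integrator is underdamped BAOAB with unit mass.
This is a deliberate choice: the binder-anchor well has a curvature of
roughly $57\varepsilon_{ab} \approx 570\,k_BT/\sigma^2$ at its minimum,
and for the overdamped Euler-Maruyama rule the corresponding
relative-coordinate relaxation rate exceeds the stability limit at any
timestep large enough to reach useful physical times
($\lambda\,\mathrm{d}t > 2$ at $\mathrm{d}t = 0.002$). BAOAB tolerates
stiff modes up to $\omega\,\mathrm{d}t \approx 2$ and has excellent
configurational accuracy, so the default $\mathrm{d}t = 0.005$ keeps the
stiffest mode at $\omega\,\mathrm{d}t \approx 0.17$ while covering 1500
time units in a 3e5-step run. Both schemes sample the same Boltzmann
distribution, and every observable in the package is configurational, so
the choice of scheme affects efficiency, not answers. The overdamped
(`"brownian"`) scheme remains available — it is exact for free diffusion
and is used for capped-force relaxation during system building (with a
0.3$\sigma$ per-step drift clamp so that rare deep-overlap kicks cannot
cascade). A pair distance below $0.3\sigma$ aborts the run as unstable
rather than silently continuing.

Initial states are built as a self-avoiding-ish random walk (step $r_0$,
rejecting sub-0.9$\sigma$ contacts) with binders and tracers placed
uniformly at random, followed by a short capped-force relaxation that
never alters the topology. Runs discard `n_equil` steps before sampling
and record a snapshot every `sample_every` steps; a radius-of-gyration
stationarity diagnostic is attached to every equilibration so that
short desk-scale runs can be judged on evidence rather than step counts.

## Observables

All contact statistics use one rule: two particles are in contact when
their minimum-image center distance is *strictly* below $t = 2\sigma$ —
the particle diameter, and a distance at which the LJ interaction is
practically zero. Ties at exactly $t$ are excluded.

* **Contact matrix** `H`: per-snapshot boolean intra-polymer contacts,
  summed over snapshots; bonded pairs ($|i-j|\le1$) are excluded because
  they are trivially always in contact. Row sums $R_i$ are the
  per-monomer "polymer contacts", the simulation analogue of a Hi-C row
  sum.
* **Tracer traffic** $C_i$: tracer-monomer contacts summed over tracers
  and snapshots — the time tracers spend at each region of the polymer.
* **Correspondence**: Pearson $r$ between $C$ and $R$ on raw counts, and
  the Kullback-Leibler divergence
  $D_{KL}(C|R)=\sum_i C_i \log(R_i/C_i)$ on profiles normalized to unit
  sum. In this orientation $D_{KL}\le 0$ and equals 0 exactly when the
  normalized profiles coincide; the package reports both the signed
  value and its magnitude, and small $|D_{KL}|$ means high
  correspondence. Monomers with $R_i = 0$ facing $C_i > 0$ receive one
  pseudo-count before normalization to keep the sum finite.
* **Coverage**: percentage of monomers visited at least once.
* **Binder exclusion**: Pearson correlation between tracer traffic and
  binder occupancy (computed with the identical contact rule).
* **Bound-time fraction**: share of (tracer, snapshot) observations
  within $t$ of any monomer — the quantity that maps $\varepsilon$ onto
  measured chromatin/nucleoplasm partitioning of real factors (50% for
  TetR gives $\varepsilon \approx 2\,k_BT$).
* **Gyration and density**: $r_{gyr}$ from unwrapped coordinates
  (reconstructed by walking the chain with minimum-image steps — wrapped
  coordinates corrupt the estimate), and
  $\rho_{local} = N(\sigma/r_{gyr})^3$.

Grid summaries average per-replicate statistics over replicates rather
than pooling profiles, so each replicate (with its own random anchor
placement) counts once.

## The genomic stage

The same physical picture is tested on real-genome summaries through two
operations. First, local chromatin compaction is estimated from a binned
contact matrix: contact probability decays locally as $s^{-\alpha}$ with
genomic separation $s$, and per 50-kb window the log signal against the
nearest 20 windows on each side (self-contacts discarded, both sides
pooled) is regressed on $\log s$; the slope estimates the local decay
exponent. Zero-signal pairs are dropped rather than pseudo-counted (log
of zero is undefined and a pseudo-count would bias clean power laws; a
pseudo-count option exists for sensitivity checks), and windows with
fewer than five usable points return a missing estimate rather than a
number. Second, interval-set enrichment at loops: HOT regions
(sub-kilobase promiscuously bound loci) are intersected with merged loop
intervals by the midpoint rule (for sub-kilobase intervals, midpoint
containment and any-overlap coincide; both rules are exposed), and the
observed count is compared with a binomial null whose success
probability is the merged loop footprint divided by genome size. The
null construction is a documented, swappable policy; a Welch two-sample
test (Welch-Satterthwaite degrees of freedom) compares decay exponents
at the query intervals against the genome-wide set.

Interval files are accepted as BED (0-based half-open), Arrowhead
domain/loop lists (both coordinate pairs of each record are parsed), and
FASTA-header locus strings (1-based closed); all are normalized into
`GRanges`, the package-wide container, so dialects are interchangeable.

## Synthetic data with known truth

Because the genomic claims should be testable without touching external
resources, the package generates both inputs with planted truth.
`synth_hic()` builds $|i-j|^{\alpha}$ matrices with a per-bin exponent
(pairs combine the two bin values by averaging, which keeps the matrix
symmetric and makes recovery exact inside patches wider than the
regression flank), log-normal noise, and Gaussian loop peaks; with noise
off, the decay estimator recovers the exponent to $10^{-6}$ across
$\alpha \in [-2.5, -0.5]$. `synth_intervals()` places loops uniformly
and each HOT midpoint inside the merged loop footprint with probability
$\rho \cdot p_{null}$, uniformly outside otherwise; at $\rho = 1$ the
marginal placement is uniform, so enrichment p-values are calibrated (a
property the test suite checks over 200 seeds), and $\rho > 1$ plants
real enrichment of known strength.

What the generators do *not* emulate: distance-dependent noise
heteroscedasticity, unmappable regions, copy-number structure,
chromosome-specific decay regimes, or correlated placement of HOTs with
other features. Passing the recovery and calibration tests therefore
demonstrates correctness of the estimators, not robustness to every
artifact of real Hi-C preprocessing — normalization is explicitly an
upstream responsibility, and the pipeline accepts any non-negative
normalized matrix.

## Desk-scale problem sizes and what they can show

The full study design (25 values of $\phi$ from 0.02 to 0.50, 10 values
of $\varepsilon$ from 0.9 to 2.7 $k_BT$, ten replicates, $10^8$ steps
each) is enumerable through `sweep_plan(phi_grid(), epsilon_grid(),
n_replicates = 10)` but is a cluster-scale campaign. The package's own
validation runs at desk scale: $N = 300$ monomers, 10 tracers,
$3\times10^5$ steps per run (snapshots every 100 steps after $10^5$
equilibration steps), three replicates — sizes chosen so a full
acceptance campaign completes on a single CPU while the contrasts of
interest remain unambiguous. At these sizes the qualitative physics is
stable and reproducible:

* the bound-time fraction rises monotonically from a few percent at
  $\varepsilon = 0.9$ to above 75% at $\varepsilon = 2.7$, crossing 50%
  close to $2\,k_BT$;
* contacts predict traffic in open, sticky conditions
  ($\phi = 0.02, \varepsilon = 2.7$: $r \approx 0.8$) and anti-predict
  it in compact, weakly bound conditions
  ($\phi = 0.50, \varepsilon = 0.9$: $r < 0$);
* coverage falls with compaction and rises with affinity, and binder
  occupancy anti-correlates with traffic in globules;
* a single loop raises traffic at its contact point 2-5-fold over the
  chain interior (the fixture assay).

Desk-scale equilibration (200-1000 time units) is far shorter than the
Rouse time of a 300-mer, so collapsed states are kinetically arrested
rather than fully equilibrated globules; the acceptance checks are
deliberately trend-level (orderings and signs, not printed values) for
this reason. The fixed-polymer control runs tracers over frozen
scaffolds — since only tracer forces are computed there, these runs are
cheap, and the package uses longer tracer-only runs ($2\times10^6$
steps) to beat the Poisson noise of hard-core contact counting, which
at $3\times10^5$ steps would swamp the contrast. The single-loop
fixture assay uses the same long-sampling protocol for a different
reason: a tracer touching both strands at the contact point sits in a
well several $k_BT$ deeper than on a single strand, so tracer exchange
happens on a $\sim10^3$-time-unit scale and short runs sample a
non-ergodic snapshot of who happens to be parked there (the measured
enhancement then converges to its equilibrium value of $\sim2$-$4$).

## Numerical choices and degenerate inputs

* Strict `<` threshold comparisons; exact-tie contacts excluded.
* Pearson correlations on zero-variance profiles are reported as `NA`
  (undefined), never coerced to 0.
* `kl_divergence()` rejects all-zero profiles; terms with $C_i = 0$
  contribute zero.
* The neighbor list is a Verlet list over linked cells (skin
  $0.4\sigma$, rebuilt when any particle has moved more than half the
  skin); it is exact with respect to an all-pairs search, a property the
  test suite asserts rather than assumes. Pairs in which both particles
  are frozen are dropped from the list, which is what makes
  fixed-polymer runs cheap.
* The engine's random stream is a self-contained xoshiro256+ generator
  seeded from the run seed, so trajectories are bit-reproducible across
  sessions and platforms regardless of the caller's R RNG state; all
  R-level placement randomness is seeded separately and restored after
  use.
* Sweep cells derive their seeds from (base seed, $\phi$, $\varepsilon$,
  replicate), making grids byte-identical across reruns and independent
  of execution order, and letting interrupted sweeps resume from
  completed per-cell files.

## Known limitations

The model is a homopolymer with uniform non-specific tracer affinity: no
binding motifs, no heteropolymer anchor strengths, no tracer-tracer
interactions, and static loops (binders effectively never unbind at
$10\,k_BT$). Tracer-induced polymer collapse at high tracer count and
affinity is outside the validated regime (the default campaigns use 10
tracers). Real-unit mappings (nm, seconds, diffusion constants) are
metadata only. The Hi-C stage accepts normalized matrices and does not
perform read-level normalization, loop calling, or HOT definition.
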