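---
title: "Modelling the evolution of mating-type switching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of mating-type switching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchsim)
```

# The biological question

Mating-type switching lets a fission yeast clone generate compatible P and
M partners from a single founding spore, so an isolated clone can complete
its sexual cycle. Heterothallic non-switchers must find a genetically
distinct partner of the opposite type, which in a spatially structured
colony means reaching the edge of their clonal patch. If switching carries
a cost during asexual growth, the balance between that cost and the mating
assurance it buys decides whether non-switchers can invade a switching
population. `switchsim` provides the three computational pieces needed to
study this balance: a lattice simulator of the competition, estimators for
measuring the cost from competition assays, and simple mutation-rate bounds
for asking how often non-switchers (or revertant switchers) arise at all.

# The cellular automaton

## State and cycle structure

The population lives on an `L x L` lattice (default 200, i.e. 40,000
sites), by default with bounded edges; a torus is available to check edge
effects. Each occupied site holds a haploid cell with: mating type (P or
M), strategy (switcher or non-switcher), switching phase (will/won't
switch; meaningful only for switchers), the clone id of its founder in the
current growth phase, an intraclonal-origin flag, and a mated flag. One
*transfer* (sexual cycle) is:

1. **Seeding.** `round(density * L^2)` uniformly random sites receive
   founders, each independently a switcher with the current switcher
   frequency, P with probability 1/2, and (if a switcher) will-switch with
   probability 1/2. Founders get unique clone ids.
2. **Growth.** Rounds of division repeat until the grid is full. Within a
   round the currently occupied sites are visited in a fresh random order;
   a cell with at least one empty Moore neighbour divides with probability
   `R` (default 0.5), multiplied by `1 - s` if it is a switcher and by `c`
   if it is of intraclonal origin. The daughter goes to a uniformly chosen
   empty neighbour; a fair coin decides which of the two resulting cells
   sits where.
3. **Mating.** Unmated cells, visited in random order, mate with a
   uniformly chosen unmated opposite-type Moore neighbour (or any unmated
   opposite-type cell in `global` mode) until no eligible pair remains.
   Strategy and clone identity are ignored — intraclonal mating is allowed,
   and is precisely the advantage switching confers.
4. **Reseeding.** Assuming Mendelian segregation at the switching locus,
   the zygote pool defines the next founder frequencies: switcher frequency
   `(2 n_SWxSW + n_SWxNS) / (2 n_zygotes)`; the intraclonal-origin
   fractions are carried per strategy with the same half-weighting of
   heterozygous zygotes.

Cycles repeat until the switcher frequency reaches 0 or 1, the zygote pool
is empty (extinction — possible in tiny populations where all cells share
one mating type), or a transfer cap (default 500) is hit.

## The switching pedigree

A will-switch mother produces exactly one switched cell: one of the two
resulting cells carries the opposite mating type and is unswitchable for
one division (won't-switch), while the other keeps the original type and
remains competent. A won't-switch mother produces one newly competent
(will-switch) cell and stays unswitchable itself. Which role lands on the
old site versus the new site is decided by the same fair coin that settles
mother-versus-daughter migration; since the two cells are otherwise
identical (clone id, intraclonal flag), a single coin suffices. This
reproduces the canonical one-in-four-granddaughters pattern while keeping
only one phase bit per cell. A sensitivity variant
(`pedigree = "bernoulli"`) instead redraws both phases i.i.d.
Bernoulli(1/2) at each division; it leaves all qualitative results in this
vignette unchanged and exists to show they do not hinge on the exact
pedigree bookkeeping.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `growthChance` (R) | per-round division probability | 0.5 | standard setting; two rounds per generation on average |
| `switchingCost` (s) | switcher division probability is `R(1-s)` | 0 | the focal cost; bounded at 0.5 so probabilities stay in range |
| `density` | fraction of sites seeded each transfer | 0.5 | controls clone-patch size (~`1/density` cells) and generations per transfer (~`log2(1/density)`) |
| `intraclonalCost` (c) | division-probability factor for intraclonal-origin founders | 1 | off by default; applies for one growth phase, cleared at the next reseeding (the minimal reading of a cost "for asexual growth") |
| `matingMode` | `moore` or `global` | moore | global mode removes all spatial structure from mating (mass action) |
| `maxGrowthRounds` | truncate the growth phase | Inf | knob for studying how much asexual growth separates sexual episodes |

Choosing `s` as a multiplier on the switcher's probability (rather than a
divisor on the non-switcher's) keeps all probabilities in `[0, R]` across
the whole allowed range; to first order in `s` the relative-fitness ratio
is the same either way.

## Update schedule and randomness

Updates are random-sequential: occupancy changes take effect immediately
within a round, each cell attempts at most one division per round, and the
visiting order is reshuffled every round. This avoids the write conflicts
a synchronous scheme would need to resolve on a shared lattice. Every
random draw in a simulation comes from R's RNG seeded once from
`SimParams@seed`, so a `(parameters, seed)` pair reproduces a trajectory
byte for byte; sweep replicates derive per-run seeds from the master seed
by a counter over a canonically sorted cell list, making results
independent of the order in which axes are supplied.

## Emergent behaviour worth knowing about

At low density, clones grow into large single-strategy patches. Switcher
patches contain both mating types and mate throughout; non-switcher patches
are a single type and mate only along contact zones with other clones. That
asymmetry is the mating advantage of switching, and it grows as density
falls:

```{r mated-fractions}
p <- SimParams(sideLength = 50, density = 0.005, maxTransfers = 1, seed = 2)
set.seed(2)
lat <- runGrowth(seedGrid(p), p)
matedFractions(lat, matingRound(lat, p))
```

At full density the growth phase is empty (the grid is seeded full), clones
are single cells, and mating is blind to strategy; strategy labels are then
exchangeable, so with `s = 0` the expected one-cycle change in switcher
frequency is exactly zero. This is the configuration used for the
neutral-drift check: at any density below 1 the model itself gives
switchers a real mating advantage even without a growth cost, so "neutral"
is only well defined without clonal structure.

## The invasion sweep

`invasionSweep()` runs a full factorial of density and cost with replicate
runs per cell and records each replicate's final non-switcher frequency.
For the packaged reproduction we use a 50 × 50 grid, a 100-transfer cap,
10 replicates per cell, densities {0.005, 0.02, 0.1, 0.4, 0.9}, costs
{0, 0.25, 0.5}, and non-switchers invading from 2% — an invasion-from-rare
design: the question is whether a rare non-switching mutant can spread in
a resident switcher population. These sizes keep a full sweep around
twenty seconds on one core while preserving the qualitative structure of
the full 200 × 200 / 500-transfer setting, which remains available through
`SimParams()`.

Two caveats of the desk scale are worth stating. First, with only 10
replicates of a 2,500-cell grid, cell means carry visible Monte-Carlo
error. Second, near the invasion boundary — and especially at density 0.9,
where the grid reseeds at 90% occupancy and a transfer therefore contains
only ~0.15 asexual generations — moderate costs produce invasions that are
still in transit at transfer 100. `polymorphismCheck()` flags such
replicates (cap reached with final frequency in `[0.1, 0.9]`); flags under
the shortened cap are transit artefacts, not evidence of stable
polymorphism: the per-transfer selection differential at density 0.9 is
roughly `s` × 0.1, so a 500-transfer run moves the frequency an order of
magnitude further in logit terms and completes the same fixations.

# Selection-coefficient estimation

`logRatioSelection()` implements the log-ratio change estimator with
natural logarithms; per-generation scaling divides by
`t = transfers × log2(fold growth)` (five transfers at 100-fold growth:
~33 generations; at 500-fold: ~45). The marker correction
`s_switching = s_total − s_marker` assumes additive coefficients, which is
exact when effects compose additively on the log-fitness scale — and the
synthetic-data generator composes them exactly that way, so the
generator/estimator round trip recovers the truth to machine precision in
the no-noise limit and within sampling error otherwise. For sexual rounds,
`sexualSelection()` returns `s = 1 − w` with `w` the ratio-change relative
fitness; the estimate is invariant to the initial mixing ratio, and no
attempt is made to decompose `w` into growth before mating, mating success
and growth after mating.

Zero counts are a hard error by default; an optional Haldane pseudocount
mode (add 0.5 to every count, flagged in the output) is available because
real flow-cytometry tables occasionally contain empty gates. Statistical
testing across groups (Kruskal–Wallis, Dunn) is deliberately left to
standard routines — the package computes estimates and standard errors,
not p-values.

# What the synthetic generator does and does not emulate

The generator mimics the structure of the competition assays: a latent
focal-strain frequency evolving deterministically under a per-generation
log-fitness difference (strain effect ± marker effect by carrier), observed
through binomial counting at fixed depth before and after — flow cytometry
counts a fixed number of events, making multinomial/binomial noise the
natural model. Reciprocally marked record sets and isogenic marker controls
come from the same machinery. An optional between-replicate jitter
(default 0) can mimic biological variance between replicate cultures; real
replicate-to-replicate variance structure is unknowable from count tables
alone. It does not emulate gating noise, debris, dead-cell background, or
density dependence within a culture — so estimator tests passing on
synthetic data validate the estimation arithmetic, not the cytometry
pipeline.

# Mutation-rate bounds

The bounds are deliberately elementary. The zero-class upper limit uses
the exact root `1 − α^(1/N)` rather than the Poisson approximation
`−log(α)/N`; both are returned and agree to within 1% for screens of 10⁴
spores or more. The independent-asci estimate samples spores without
replacement (spores are physical objects) and reports the Monte-Carlo mean
next to the hypergeometric closed form
`n_asci × (1 − C(T−4, k)/C(T, k))`. One published inconsistency is
preserved rather than reconciled: a bottleneck loss probability printed as
0.37 is consistent with `n·f = 1` (≈ e⁻¹) but not with the printed
parameters `n = 5×10⁸, f = 5×10⁻⁸` (which give e⁻²⁵);
`subsampleLossProbability()` exposes both evaluations and the choice is the
caller's.

# Numerical choices and degenerate inputs

* Growth that cannot fill the grid (effective division probability
  numerically zero) trips a round safeguard of `L² × 1000` rounds and
  raises an error rather than spinning forever.
* A seeding that would place fewer than two founders is a configuration
  error caught at parameter validation.
* An empty zygote pool is a distinct extinction condition
  (`switchsim_extinction`), recorded in trajectories as
  `termination = "extinct"`; extinct replicates are excluded from sweep
  means and counted separately, since the mean final frequency of a
  population that no longer exists is not meaningful.
* A starting switcher frequency of exactly 0 or 1 is absorbing; the run
  executes one full cycle and terminates as fixed. Both absorbing states
  are treated symmetrically.
* Greedy random mating produces a *maximal* matching, which can be smaller
  than a *maximum* matching on dense mixed neighbourhoods; the test suite
  checks the greedy outcome against an independent augmenting-path oracle
  as an upper bound, and in `global` mode the greedy process provably
  attains `min(n_P, n_M)` pairs.

# Problem sizes used by the packaged checks

The automated checks run the neutral-symmetry test on a 30 × 30 grid with
200 replicates, the invasion sweep at the 50 × 50 / 100-transfer scale
described above, the mating-advantage comparison on ten 50 × 50 grids at
density 0.005, estimator recovery at depth 10⁵ with 8 replicates, and the
asci resampling at the full 2.5 × 10⁶-asci scale. These sizes were chosen
so the whole suite completes in about a minute of simulation time while
keeping Monte-Carlo error well below the effect sizes being checked.

# Known limitations

* Haploid lattice cells only: no diploid vegetative growth, sporulation
  kinetics, pheromone signalling or nutrient dynamics.
* One division attempt per cell per round makes "generation" an emergent
  quantity (`~log2(1/density)` per transfer); there is no wall-clock time.
* The mating rule is all-or-nothing within a round; partial mating
  efficiency or distance-dependent pheromone attraction is not modelled.
* The estimators assume constant selection over the assay; frequency- or
  phase-dependent growth shows up as bias, not as a diagnostic.
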