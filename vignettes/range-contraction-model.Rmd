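---
title: "The range-contraction model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The range-contraction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rangesim` simulates a generalist species in continuous two-dimensional space
whose geographic range contracts in one of three patterns — shrinkage
(periphery to core), amputation (an extinction front advancing from one
edge), or fragmentation (loss of continuity leaving disjunct patches) — and
measures the demographic and population-genetic consequences. This vignette
is the package's own account of the model: what is simulated, which knobs
matter, what the defaults mean, and where the design was genuinely open.

## The individual-based model

Space is a rectangle of `nx x ny` unit cells (default 20 x 20 distance
units). Each cell carries a habitat fitness `h` in (0, 1]; before contraction
all cells have `h = 1`, and a contraction event drops the scheduled cells to
`h = 0.1`. Fitness at a continuous position is the bilinear interpolation of
the four surrounding cell-center values, so habitat quality changes smoothly
rather than in steps. Contracted habitat is hostile but not instantly lethal.

Individuals are diploid, hermaphroditic, self-incompatible, and sessile after
natal dispersal. Interactions are mediated by a truncated Gaussian kernel
with scale `sigma`: the interaction strength at distance `d` is
`m * exp(-d^2 / (2 sigma^2))` with maximum `m = 1 / (2 pi sigma^2)`, and is
exactly zero at and beyond `3 sigma`. The same kernel governs mate choice and
competition, and `sigma` is also the natal dispersal scale — one scale
controls all spatial behaviour.

Each timestep applies, in fixed order:

1. **Contraction.** Any scheduled event drops its cells to `h = 0.1`.
2. **Reproduction.** Every living individual, as focal parent, picks one mate
   among neighbours within `3 sigma` with probability proportional to the
   kernel (none available: no offspring this step), then draws a number of
   offspring from Poisson(`lambda`) with `lambda = 1/L`.
3. **Dispersal.** Each newborn moves by independent Normal(0, `sigma`)
   displacements per axis, once, immediately after birth. Boundaries are
   absorbing: a newborn landing outside the range dies and is recorded as a
   boundary death. Adults never move.
4. **Survival.** Every individual — adults and this step's newborns alike —
   survives with probability
   `W = 1 / (1 + rho * C / h)`, where `C` is its competition load,
   `h` the habitat fitness at its position, and
   `rho = lambda / ((1 + lambda) K)` the spatial competition constant.
   The competition load is the kernel sum over all neighbours within
   `3 sigma`, multiplied by an edge correction: the full interaction-disc
   area divided by the exact area of the disc clipped to the range rectangle
   (closed-form circle–rectangle intersection), so that individuals near an
   edge perceive density relative to the space actually occupiable.
5. **Ages** are timesteps since birth (a newborn is 0 at its birth census).
6. **Recording.** Abundance, births, boundary deaths, mean and maximum age,
   and the mean lifetime offspring tally of living individuals.

With this survival rule the demographic equilibrium is transparent: at
stationarity survival must balance fecundity, `W (1 + lambda) = 1`, which
solves to a local density of `h K` — carrying capacity `K` per cell on intact
habitat, `K/10` in contracted habitat — and a standing mean age of `L`. Both
are verified as tests, not assumed. Newborns compete in the timestep they are
born, which is what makes the density regulation land at `K` rather than
overshoot.

Reading the survival formula's competition term as the *summed* kernel load
rather than the kernel maximum is deliberate: the constant-maximum reading
would make survival density-independent, contradicting the model's
density-dependent design, and would admit no equilibrium at `K`.

## Contraction schedules

A schedule removes `frac_per_event` of all cells per event (default 0.22)
in `n_events` discrete events (default 4) spaced `interval` timesteps apart
(default 100) — 88% of the range in total at the defaults. The cell
geometries are deterministic and versioned in code:

- **shrinkage** removes the most peripheral cells first (largest Chebyshev
  distance to a centered 8 x 6 remnant block), leaving the centered block;
- **amputation** removes columns from the left edge; the remnant strip hugs
  the right edge and spans the full range height, so the extinction front
  sweeps the long axis. The four sampling bands (`top` … `lower`) lie along
  that axis; a remnant banded across its short (~2.4-unit) dimension would
  put all band centroids within one interaction radius of each other and
  could not express isolation by distance;
- **fragmentation** removes cells from the range center outward, severing
  connectivity early and leaving four corner patches (two of 16 cells, two
  of 8) with nothing habitable in the center;
- **random_fragmentation** removes uniformly random cells (seeded), as a
  control for the specific fragmentation geometry.

Custom geometries can be supplied as explicit cell sets and schedules
round-trip through YAML.

## Genetics

Genomes are haploid length `genome_length` per chromosome set, with
infinite-sites mutations at continuous positions and crossover recombination.
Each gamete draws Poisson(`rec * genome_length`) breakpoints and
Poisson(`mu * genome_length`) new mutations. The desk profile (1e7 bp,
`mu = 1e-6`, `rec = 1e-7`) preserves the full-scale per-gamete means — about
10 new mutations and 1 crossover per gamete — at 1% of the bookkeeping cost;
the paper-scale profile (1e9 bp, `mu = 1e-8`, `rec = 1e-9`) is retained in
the configuration for cluster use.

Rather than running the tens of thousands of timesteps needed for neutral
diversity to equilibrate from scratch, the simulator injects founder
diversity once, during the burn-in: every haplotype present becomes a
founder, and a shared pool of segregating sites is generated with site
frequencies drawn from the neutral equilibrium spectrum (probability of k
copies proportional to 1/k) such that the expected pairwise difference per
site between two random founder haplotypes equals `theta`. This is the
forward-in-time analogue of completing the burn-in with a coalescent: it
sets diversity at mutation–drift balance instantly. The desk default
`theta = 4e-3` corresponds to an effective population size of about half the
census (`theta = 4 Ne mu` with `Ne ~ 1000` of ~2000 individuals);
reproductive variance and spatial structure put the realized effective size
below the census count, and the package's reported quantities — *relative*
diversity declines and F_ST — are insensitive to the injected level because
they are drift-dominated. The injection is spatially random, so local
genetic structure (isolation by distance, edge effects) needs time to
develop afterwards: the desk profile runs 800 timesteps (~200 generations)
of genetic settling between injection and the first contraction event,
enough for mean individual heterozygosity to reach its spatial plateau; with
a much shorter settling phase the no-contraction control drifts downward and
contaminates the measured declines.

Haplotypes carry their founder material as ancestry segments referencing the
shared pool, plus explicit post-injection mutations; sampled haplotypes are
reconstructed to explicit mutation lists at sampling time. This is exactly
equivalent to storing full per-haplotype mutation lists (segments tile the
genome; sites are unique), at a small fraction of the memory and per-gamete
cost.

Pedigrees are recorded completely. Kinship is computed by the tabular method
truncated at 10 generations, with inbreeding ignored in the recursion
(diagonal relatedness fixed at 1) — the convention under which the sample
relatedness summary `F_r = (r - n)/n` is zero for mutually unrelated
individuals. Contributions beyond 10 generations are below 2^-10 and
negligible at the sampling cadence used. When ancestry tracking is enabled,
every gamete's splice intervals are recorded from 50 timesteps before the
first event, so the genomic contribution of every individual alive at any
later time slice to any sampled descendant can be recovered exactly; the
contributions necessarily sum to one, which doubles as a conservation check
on the segment bookkeeping.

## Sampling and statistics

The default sampling plan mirrors the analysis workflow: 100 random
individuals 50 timesteps before the first event (with a separate random 50
as the "ancient" reference), 100 random individuals 50 timesteps after each
event and at the final timestep, 50 individuals per named region group at
the final timestep, and 4 random descendants 100 timesteps after the last
event for the spatial-ancestry clouds. Sampling uses an RNG stream
independent of the simulation stream, so analyses can be re-drawn without
re-simulating. If a region holds fewer than 50 living individuals, all are
taken and the shortfall is warned about rather than failing the run.

Statistics follow the standard estimators: individual heterozygosity (the
per-site count of positions carried by exactly one of an individual's two
haplotypes); group nucleotide diversity as the mean pairwise difference over
all `choose(2n, 2)` haplotype pairs (a flag restricts to between-individual
pairs, an O(1/n) difference); cross-group divergence `pi12`; and
`F_ST = 1 - 2(pi1 + pi2) / (pi1 + 2 pi12 + pi2)`. Group comparisons use
unpaired Wilcoxon rank-sum tests (groups at different times are different
individuals) with Holm adjustment, preceded by a Shapiro–Wilk normality
check; trend summaries are ordinary least squares on timestep.

The diversity *timecourse* is reported as the group mean of individual
heterozygosity relative to the same replicate's pre-contraction mean. The
choice matters: once remnants are spatially differentiated, the pooled
pairwise diversity of a range-wide random sample retains all the
between-patch divergence and barely declines even when every patch has fixed
a different set of lineages, whereas mean individual heterozygosity measures
the local diversity that is actually being lost. Both are computed; the
pooled value is reported alongside.

## Parameters that matter

| Parameter | Default (desk) | Units | Why |
|---|---|---|---|
| `nx`, `ny` | 20 x 20 | cells | range of 400 cells, 1 unit per cell side |
| `K` | 5 | individuals/cell | demographic equilibrium density on intact habitat |
| `L` | 4 | timesteps | mean age; fecundity is `lambda = 1/L = 0.25` |
| `sigma` | 0.5 | cell sides | dispersal, mating and competition scale; sets neighbourhood size ~ `4 pi sigma^2 K` ~ 16 and hence the strength of isolation by distance |
| `genome_length` | 1e7 | bp | with `mu = 1e-6`, `rec = 1e-7`: 10 mutations, 1 crossover per gamete |
| `theta` | 4e-3 | per site | injected founder diversity (see above) |
| `burn_in` | 1000 | timesteps | 200 demographic + 800 genetic settling |
| `post_run` | 400 | timesteps | observation window after the last event |
| replicates | 3 | — | desk default; paper profile stores 10 |

`sigma` deserves a caution. It is not printed in the source material for
this model family; 0.5 cell sides gives a Wright neighbourhood of ~16
individuals and reproduces strong isolation by distance across the
amputation remnant (maximum band-pair F_ST ~ 0.3–0.4). A larger `sigma`
would slow local heterozygosity loss and weaken F_ST roughly in proportion.
Several reported behaviours trade off against each other through this single
knob, and at `sigma = 0.5` the model errs on the side of strong spatial
structure: local diversity declines in the shrinkage and amputation remnants
are steeper than a weakly structured model would give, and even the
shrinkage core shows measurable (if small) distance–F_ST correlation. The
claim that a lineage can traverse the 20-unit range in ~40 timesteps is
unattainable under any `sigma` compatible with strong isolation by distance
(40 dispersal draws of scale 0.5 travel ~3 units rms); the package instead
verifies that lineage spread grows with pedigree depth, the random-walk
property actually available at this scale.

## What the generator emulates, and what it does not

The simulator *is* the data source: there is no external input. It emulates
density regulation around a carrying capacity, overlapping generations,
kernel-limited mating and competition with exact edge correction, absorbing
boundaries, discrete-interval contraction to low (not zero) habitat fitness,
neutral diploid genomes at mutation–drift balance, and complete pedigree and
ancestry bookkeeping. It does not emulate: separate sexes or mate limitation
beyond the kernel (no Allee effects), adult movement, habitat selection or
preference, selection on genomes, age-specific vital rates, heterogeneous
pre-contraction habitat, or continuous (non-discrete) contraction. Passing
tests therefore say nothing about systems where those forces dominate; they
say the package faithfully computes the consequences of *this* model.

One behaviour of the printed survival rule is worth knowing when comparing
with coarser expectations: contracted habitat at `h = 0.1` supports a sparse
standing population at `~K/10` rather than emptying. Roughly one third of the
post-contraction population therefore lives outside the remnant at desk
scale, which caps the realized range-wide abundance decline near
`1 - (0.12 + 0.88 * 0.1) ~ 80%` plus sparse-zone attrition, i.e. just above
82% rather than 86–88%. The shrinkage remnant additionally sits in the range
interior, where it pays no boundary-death toll, making shrinkage the least
depleted scenario by one to two points.

## Numerical choices

- Bilinear interpolation clamps to the outermost cell centers (constant
  extrapolation in the half-cell border band), keeping values within the
  cell-value extrema everywhere.
- The circle–rectangle intersection is evaluated in closed form via corner
  decomposition of the disc area under two half-plane constraints; it is
  exact at corners and edges (quarter and half discs) and is
  cross-checked against Monte-Carlo rejection sampling in the tests.
- Mutation positions are continuous doubles; recurrent mutation has
  probability zero and positions are compared exactly.
- Poisson draws use R's RNG; the whole run is bit-reproducible from one
  integer seed. Genotype sampling uses a separate mt19937-based stream with
  an implementation-independent bounded-draw, so sampling is reproducible
  across platforms and independent of the simulation stream.
- VCF export rounds positions to integer base pairs and bumps the rare
  collisions to the next free position, preserving all pairwise genotype
  differences exactly; statistics recomputed from the VCF match the
  in-memory values bit for bit.
- Extinction (N = 0) terminates a run early with the partial time series
  preserved and the replicate excluded from experiment aggregates with a
  warning. Note that a lone individual with an empty neighbourhood has
  survival 1 under the model's survival rule, so true extinction requires a
  correlated collapse.

## Problem sizes

The desk profile used by the tests and the acceptance script runs 20 x 20
cells at `K = 5` (about 1,900 individuals at equilibrium), 1,000 burn-in
timesteps, four events 100 timesteps apart, and a 400-timestep
post-contraction window — 1,700 timesteps per run, three replicates per
scenario, with 1e7-bp genomes. One run takes tens of seconds and under
3 GB of memory; the full three-scenario experiment completes in minutes.
These sizes were chosen as the smallest at which the spatial-genetic
signals of interest (isolation by distance, patch differentiation,
local heterozygosity loss) are comfortably larger than replicate noise.

## Known limitations

- Absolute diversity levels are configuration-dependent (via `theta`); only
  relative declines and differentiation are meaningful outputs.
- The desk-scale timeline compresses the pre-contraction history; deep
  ancestral structure beyond the injected equilibrium is absent.
- With `sigma = 0.5` the model sits at the strongly structured end of the
  plausible range (see above); magnitude comparisons for weakly structured
  systems should rescale `sigma` and re-run.
- The sparse population retained in contracted habitat is a genuine
  prediction of the printed survival rule, but real systems in which
  degraded habitat is lethal rather than poor will show deeper abundance
  declines than this model.
- Hermaphroditic selfing-free mating with one focal-parent draw per
  individual per timestep means a pair can be counted twice in one timestep
  only as two independent focal draws.
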