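# rangesim

Forward-time, spatially explicit simulation of **range contraction** and its
demographic and genetic consequences, for conservation and population
geneticists who want mechanistic expectations rather than verbal arguments.

Species ranges rarely just "get smaller": they **shrink** from the periphery
toward the core, they are **amputated** by an extinction front advancing from
one edge, or they **fragment** into disjunct patches. `rangesim` simulates a
generalist species under each pattern in continuous 2-D space and computes
the downstream quantities a population-genetic analysis would measure:
abundance and age structure, pedigree relatedness, nucleotide diversity
within and between sampled groups, F<sub>ST</sub>, and the spatial
distribution of genetic ancestry.

## The model in brief

Individuals are diploid hermaphrodites with overlapping generations on an
`nx x ny` habitat grid (default 20 x 20, one distance unit per cell side,
habitat fitness interpolated bilinearly between cell centers). Mate choice
and competition use a truncated Gaussian kernel with scale σ (maximum
`1/(2πσ²)`, zero beyond 3σ); pairs produce Poisson(λ) offspring with
λ = 1/L; newborns disperse once by Normal(0, σ) per axis with absorbing
range boundaries; and every individual survives each timestep with
probability

W = 1 / (1 + ρ C / h),  ρ = λ / ((1 + λ) K),

where C is the edge-corrected kernel sum over neighbours (exact
circle–rectangle clipping at range edges) and h the local habitat fitness.
This regulates density at `h·K` per cell and the mean age at L. A
contraction schedule drops 22% of cells to h = 0.1 in four events 100
timesteps apart (88% total range loss). Genomes are neutral infinite-sites
sequences with recombination (~10 new mutations and ~1 crossover per gamete
at both the desk- and full-scale parameterizations); founder diversity is
injected at a neutral-spectrum mutation–drift equilibrium during burn-in,
and complete pedigrees plus recombination-segment ancestry are recorded.
Group statistics are π, π₁₂ and

F_ST = 1 − 2(π₁ + π₂) / (π₁ + 2π₁₂ + π₂),

with unpaired Wilcoxon rank-sum comparisons (Holm-adjusted) for group
contrasts and Wright-style pedigree relatedness summarized as
F_r = (r − n)/n. See the vignette
(`vignettes/range-contraction-model.Rmd`) for the full account.

## Worked example

```r
library(rangesim)

p   <- sim_params()                      # desk profile: 20x20, K = 5, L = 4
sim <- simulate_range("fragmentation", p, seed = 7)
summary(sim)
#> range-contraction run ('fragmentation')
#>   pre-contraction mean N : 1899.9
#>   final mean N           : 316.1
#>   population decline     : 83.4%

pre <- mean(individual_heterozygosity(sim$samples$pre))
fin <- mean(individual_heterozygosity(sim$samples$final))
round(100 * (1 - fin / pre), 1)          # % loss of individual diversity
#> [1] 64.5

ft <- fst_table(sim)                     # remnant corner patches + "ancient"
subset(ft, group1 != "ancient" & group2 != "ancient",
       select = c(group1, group2, fst))
#>       group1      group2       fst
#> 1 bottomleft    topright 0.5376943
#> 2 bottomleft     topleft 0.5875386
#> 3 bottomleft bottomright 0.6711394
#> 5   topright     topleft 0.6714556
#> 6   topright bottomright 0.7392664
#> 8    topleft bottomright 0.8392061
```

The population falls by ~83% (tracking the 88% habitat loss, less the sparse
population that persists on degraded habitat), individuals lose most of
their heterozygosity as each isolated patch fixes its own lineages, and
every patch pair is strongly differentiated (F<sub>ST</sub> ≫ 0), the
signature of fragmentation as opposed to shrinkage (which keeps a single
well-mixed core) or amputation (which shows isolation by distance along the
remnant strip instead).

Other entry points: `run_experiment()` (scenario × replicate grids with
aggregation), `diversity_timecourse()`, `relatedness_series()`,
`ancestry_cloud()` (spatial ancestry of sampled descendants),
`write_outputs()` (TSV/CSV/VCF/JSON exports), `load_config()` (YAML
configuration).

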