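# Shared simulation fixtures, built lazily once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# quick engine-level parameters: a small genome, injection early in the
# burn-in so local genetic structure is settled before any sampling, and an
# injected diversity consistent with the fixture's own mutation-drift balance
tiny_params <- function(...) {
  sim_params(burn_in = 300, genetics_burn_in = 280, post_run = 60,
             genome_length = 1e6, mu = 1e-6, rec = 1e-6, theta = 4e-3, ...)
}

# small tracked shrinkage run on an 8x8 grid (ancestry, VCF, IO tests)
tiny_genetic_sim <- function() cached("tiny_gen", function() {
  suppressWarnings(simulate_range("shrinkage", tiny_params(), seed = 5,
                                  nx = 8, ny = 8, track_ancestry = TRUE))
})

# uncontracted 20x20 demographic run (equilibrium / dispersal tests)
equilibrium_sim <- function() cached("equilibrium", function() {
  p <- sim_params(burn_in = 250, genetics_burn_in = 0, post_run = 50)
  simulate_range("none", p, seed = 3, genetics = FALSE, region_samples = FALSE)
})

# the desk-scale experiment behind the acceptance criteria (several minutes)
acceptance_experiment <- function() cached("acc_exp", function() {
  suppressWarnings(run_experiment(
    c("shrinkage", "amputation", "fragmentation"),
    params = sim_params(), n_replicates = 3, master_seed = 1,
    relatedness = TRUE, relatedness_cadence = 50L,
    relatedness_replicates = 1L))
})

# brute-force symmetric-difference count between two sorted position vectors
brute_diff <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))

# brute-force group diversity: mean pairwise difference over all haplotype
# pairs (independent of the packaged bitset implementation)
brute_pi <- function(haps, L) {
  n <- length(haps)
  tot <- 0; k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + brute_diff(haps[[i]], haps[[j]]); k <- k + 1
  }
  tot / k / L
}
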