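# small synthetic haplotype fixtures built in code
fake_sample <- function(hap1, hap2, L = 1e4) {
  n <- length(hap1)
  structure(list(label = "fixture", timestep = 0L, requested_n = n,
                 ids = seq_len(n), x = rep(0, n), y = rep(0, n),
                 age = rep(1L, n), arg1 = NULL, arg2 = NULL,
                 hap1 = hap1, hap2 = hap2),
            genome_length = L, class = "hap_sample")
}

random_haps <- function(n, pool, mean_k = 6) {
  lapply(seq_len(n), function(i) sort(sample(pool, rpois(1, mean_k))))
}

test_that("individual heterozygosity counts one-haplotype-only positions", {
  s <- fake_sample(list(c(1, 2, 3), c(10, 20)), list(c(1, 2, 3), c(20, 30, 40)),
                   L = 1e7)
  expect_equal(individual_heterozygosity(s), c(0, 3 / 1e7))
  s5 <- fake_sample(list(sort(runif(5, 0, 1e7))), list(numeric(0)), L = 1e7)
  expect_equal(individual_heterozygosity(s5), 5e-7)
  # internal consistency: equals the pairwise difference of its own haplotypes
  set.seed(1)
  pool <- runif(40, 0, 1e4)
  h1 <- random_haps(4, pool); h2 <- random_haps(4, pool)
  s <- fake_sample(h1, h2)
  expect_equal(individual_heterozygosity(s),
               mapply(function(a, b) brute_diff(a, b) / 1e4, h1, h2))
})

test_that("group diversity matches the exhaustive-pair oracle", {
  # degenerate: identical haplotypes
  s0 <- fake_sample(list(c(1, 5), c(1, 5)), list(c(1, 5), c(1, 5)))
  expect_equal(nucleotide_diversity(s0), 0)

  set.seed(2)
  for (rep in 1:5) {
    pool <- runif(30, 0, 1e4)
    h1 <- random_haps(4, pool); h2 <- random_haps(4, pool)
    s <- fake_sample(h1, h2)
    expect_equal(nucleotide_diversity(s), brute_pi(c(h1, h2), 1e4))
    # invariant to relabelling individuals
    perm <- sample(4)
    expect_equal(nucleotide_diversity(fake_sample(h1[perm], h2[perm])),
                 nucleotide_diversity(s))
    # between-individual-only variant differs by the within-individual pairs
    D_all <- nucleotide_diversity(s)
    D_btw <- nucleotide_diversity(s, within_individual_pairs = FALSE)
    expect_true(is.finite(D_btw) && D_btw >= 0)
  }
  expect_error(nucleotide_diversity(fake_sample(list(c(1)), list(c(2)))),
               ">= 2")
})

test_that("pairwise divergence matches the brute-force cross loop", {
  L <- 1e4
  # fully distinct fixed mutation sets of size k
  g1 <- fake_sample(list(c(1, 2, 3)), list(c(1, 2, 3)), L)
  g2 <- fake_sample(list(c(7, 8, 9)), list(c(7, 8, 9)), L)
  expect_equal(pairwise_divergence(g1, g2), 6 / L)
  # self-comparison of a pooled identical set equals its within-pi only in
  # the degenerate identical-haplotype case
  expect_equal(pairwise_divergence(g1, g1), 0)

  set.seed(3)
  pool <- runif(25, 0, L)
  a1 <- random_haps(3, pool); a2 <- random_haps(3, pool)
  b1 <- random_haps(2, pool); b2 <- random_haps(2, pool)
  ga <- fake_sample(a1, a2); gb <- fake_sample(b1, b2)
  ha <- c(a1, a2); hb <- c(b1, b2)
  tot <- 0
  for (i in seq_along(ha)) for (j in seq_along(hb))
    tot <- tot + brute_diff(ha[[i]], hb[[j]])
  expect_equal(pairwise_divergence(ga, gb), tot / (length(ha) * length(hb)) / L)
})

test_that("F_ST closed forms and monotonicity", {
  expect_equal(fst_nei(0.01, 0.01, 0.01), 0)
  expect_equal(fst_nei(0, 0, 0.3), 1)
  expect_equal(fst_nei(0.01, 0.01, 0.02), 1 / 3)
  p12 <- seq(0.01, 0.1, by = 0.01)
  expect_true(all(diff(fst_nei(0.01, 0.01, p12)) > 0))
  expect_error(fst_nei(-0.1, 0, 0.1), ">= 0")
  expect_warning(out <- fst_nei(0, 0, 0), "denominator")
  expect_true(is.na(out))
})

test_that("normality check flags heavy tails, passes Gaussian samples", {
  expect_error(normality_check(rep(1, 10)))        # degenerate
  expect_error(normality_check(c(1, 2)), "at least 3")
  set.seed(4)
  expect_gt(normality_check(rnorm(200))$p.value, 1e-3)
  hits <- 0
  for (i in 1:20) if (normality_check(rt(500, df = 1))$p.value < 0.01)
    hits <- hits + 1
  expect_gte(hits, 19)
})

test_that("pairwise Wilcoxon: exact separation p-value and matrix shape", {
  set.seed(5)
  v <- c(rnorm(10), rnorm(10))
  g <- rep(c("a", "b"), each = 10)
  # identical groups
  m0 <- pairwise_wilcoxon(c(1:10, 1:10), g)
  expect_equal(m0["a", "b"], 1)
  # complete separation: exact two-sided rank-sum null by enumeration
  m1 <- pairwise_wilcoxon(c(1:10, 101:110), g)
  expect_equal(m1["a", "b"], 2 / choose(20, 10), tolerance = 1e-12)
  # symmetry, unit diagonal, three groups
  v3 <- rnorm(30); g3 <- rep(letters[1:3], each = 10)
  m3 <- pairwise_wilcoxon(v3, g3)
  expect_equal(m3, t(m3))
  expect_equal(unname(diag(m3)), rep(1, 3))
  expect_error(pairwise_wilcoxon(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})

test_that("trend fit agrees with the closed-form normal equations", {
  t5 <- c(1, 2, 4, 7, 11); y5 <- c(2.0, 2.3, 3.1, 4.0, 6.2)
  ft <- trend_fit(t5, y5)
  slope_hand <- sum((t5 - mean(t5)) * (y5 - mean(y5))) / sum((t5 - mean(t5))^2)
  expect_equal(ft$slope, slope_hand)
  r2_hand <- stats::cor(t5, y5)^2
  expect_equal(ft$r_squared, r2_hand)

  # perfectly linear
  expect_equal(trend_fit(1:10, 2 + 3 * (1:10))$r_squared, 1)
  # permuted response: near-uniform p-values
  set.seed(6)
  x <- 1:40; y <- 2 + 0.5 * x + rnorm(40)
  ps <- replicate(200, trend_fit(x, sample(y))$p_value)
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps < 0.5), 0.3)
  expect_error(trend_fit(c(1, 1, 1), 1:3), "constant")
  expect_error(trend_fit(1:2, 1:2), "at least 3")
})
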