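test_that("gamete formation: identity case and Poisson draw counts", {
  p <- sim_params()   # desk profile: 1e7 bp, 10 mutations, 1 crossover
  h1 <- sort(runif(50, 0, p$genome_length))
  h2 <- sort(runif(40, 0, p$genome_length))

  # zero rates: the gamete is exactly one parental haplotype
  p0 <- sim_params(mu = 0, rec = 0)
  set.seed(1)
  for (i in 1:10) {
    g <- make_gametes(h1, h2, p0)$gametes[[1]]
    expect_true(identical(g, h1) || identical(g, h2))
  }

  # per-gamete means at both parameterizations (exact products)
  expect_equal(p$genome_length * p$mu, 10)
  expect_equal(p$genome_length * p$rec, 1)
  pp <- sim_params("paper")
  expect_equal(pp$genome_length * pp$mu, 10)
  expect_equal(pp$genome_length * pp$rec, 1)

  # chi-square goodness of fit of counts to their Poisson laws
  set.seed(2)
  gg <- make_gametes(h1, h2, p, n = 10000)
  for (counts_lambda in list(list(gg$n_new_mutations, 10),
                             list(gg$n_breakpoints, 1))) {
    x <- counts_lambda[[1]]; lam <- counts_lambda[[2]]
    expect_equal(mean(x), lam, tolerance = 3 * sqrt(lam / 1e4) / lam)
    kmax <- max(x)
    obs <- tabulate(x + 1L, nbins = kmax + 1L)
    pr <- dpois(0:kmax, lam); pr[kmax + 1L] <- 1 - ppois(kmax - 1L, lam)
    keep <- pr * 1e4 >= 5
    chi <- sum((obs[keep] - 1e4 * pr[keep])^2 / (1e4 * pr[keep]))
    expect_gt(pchisq(chi, sum(keep) - 1L, lower.tail = FALSE), 0.01)
  }

  # inherited mutations come from the parents only
  set.seed(3)
  g <- make_gametes(h1, h2, sim_params(mu = 0), n = 20)
  for (gm in g$gametes) expect_true(all(gm %in% c(h1, h2)))
})

test_that("founder-diversity injection hits the requested diversity", {
  # engine run that stops right at genetics activation
  p <- sim_params(burn_in = 30, genetics_burn_in = 0, post_run = 0,
                  genome_length = 1e6, mu = 0, rec = 0, theta = 1e-3)
  s <- suppressWarnings(simulate_range("none", p, seed = 9, nx = 5, ny = 5,
                                       region_samples = FALSE,
                   extra_samples = list(list(t = 30, n = 50, label = "now"))))
  smp <- s$samples$now
  expect_gt(length(smp$ids), 20)
  expect_equal(nucleotide_diversity(smp), 1e-3, tolerance = 0.1)
  expect_error(sim_params(theta = 0), "theta")
})

test_that("pedigree kinship identities", {
  ped <- data.frame(
    id = 1:8,
    parent1 = c(NA, NA, NA, NA, 1L, 1L, 1L, 5L),
    parent2 = c(NA, NA, NA, NA, 2L, 2L, 3L, 4L),
    birth = c(0, 0, 0, 0, 1, 1, 1, 2))
  expect_equal(kinship(1, 2, ped), 0)               # unrelated founders
  expect_equal(kinship(1, 5, ped), 0.25)            # parent-offspring
  expect_equal(kinship(5, 6, ped), 0.25)            # full sibs
  expect_equal(kinship(5, 7, ped), 0.125)           # half sibs
  expect_equal(kinship(2, 8, ped), 0.125)           # grandparent via 5 only
  expect_equal(kinship(5, 5, ped), 0.5)             # self, non-inbred
  expect_equal(relatedness_matrix(c(1, 5), ped)[1, 2], 0.5)
  expect_equal(unname(diag(relatedness_matrix(5:8, ped))), rep(1, 4))
  expect_error(kinship(1, 99, ped), "unknown")

  # F_r summaries
  expect_equal(mean_relatedness(1:4, ped), 0)               # unrelated
  expect_equal(mean_relatedness(c(1, 5), ped), 0.5)         # parent-offspring
  expect_error(mean_relatedness(1, ped), "at least 2")

  # truncation: beyond max_depth ancestors are treated as founders
  expect_equal(kinship(2, 8, ped, max_depth = 1), 0)
})

test_that("kinship matches a gene-dropping simulation on a random pedigree", {
  set.seed(11)
  # Random multi-generation pedigree without inbreeding loops: mating pairs
  # are always drawn from ancestrally disjoint family branches (a binary
  # family-merging design), so the non-inbred kinship recursion is exact and
  # comparable to gene dropping. Sibship sizes are random.
  ngen <- 4
  id <- integer(0); p1 <- integer(0); p2 <- integer(0); gen <- integer(0)
  branch <- integer(0)                  # family-branch label per individual
  nb <- 2^(ngen - 1)                    # founder branches
  for (b in seq_len(nb * 2)) {          # two founders per branch
    id <- c(id, length(id) + 1L); p1 <- c(p1, NA_integer_)
    p2 <- c(p2, NA_integer_); gen <- c(gen, 1L)
    branch <- c(branch, (b + 1L) %/% 2L)
  }
  for (g in 2:ngen) {
    nb_g <- 2^(ngen - g)
    for (b in seq_len(nb_g)) {
      # one random parent from each of two sub-branches of generation g-1
      cand1 <- id[gen == g - 1L & branch == 2L * b - 1L]
      cand2 <- id[gen == g - 1L & branch == 2L * b]
      pa <- if (length(cand1) > 1) sample(cand1, 1) else cand1
      pb <- if (length(cand2) > 1) sample(cand2, 1) else cand2
      for (k in seq_len(sample(2:4, 1))) {
        id <- c(id, length(id) + 1L); p1 <- c(p1, pa); p2 <- c(p2, pb)
        gen <- c(gen, g); branch <- c(branch, b)
      }
    }
  }
  ped <- data.frame(id = id, parent1 = p1, parent2 = p2, birth = gen)

  ndrop <- 1e5
  a1 <- matrix(0L, ndrop, length(id)); a2 <- matrix(0L, ndrop, length(id))
  for (i in id) {
    if (is.na(p1[i])) { a1[, i] <- 2L * i; a2[, i] <- 2L * i + 1L }
    else {
      pick1 <- runif(ndrop) < 0.5
      a1[, i] <- ifelse(pick1, a1[, p1[i]], a2[, p1[i]])
      pick2 <- runif(ndrop) < 0.5
      a2[, i] <- ifelse(pick2, a1[, p2[i]], a2[, p2[i]])
    }
  }
  test_ids <- id[gen >= 3]
  km <- kinship_matrix(test_ids, ped, max_depth = 10)
  nt <- length(test_ids)
  for (pair in list(c(1, 2), c(1, nt), c(2, nt - 1))) {
    a <- test_ids[pair[1]]; b <- test_ids[pair[2]]
    ibd <- (a1[, a] == a1[, b]) + (a1[, a] == a2[, b]) +
           (a2[, a] == a1[, b]) + (a2[, a] == a2[, b])
    est <- mean(ibd) / 4
    se <- stats::sd(ibd / 4) / sqrt(ndrop)
    expect_lt(abs(km[as.character(a), as.character(b)] - est), 3 * se + 1e-6)
  }
})

test_that("relatedness series and non-negativity under truncation", {
  sim <- tiny_genetic_sim()
  rs <- relatedness_series(sim, n = 30, cadence = 60, seed = 2)
  expect_true(all(is.finite(rs$Fr)))
  expect_true(all(rs$Fr >= 0))                 # non-negative matrix entries
  set.seed(4)
  ids <- sample(alive_at(sim$pedigree, sim$n_steps), 20)
  expect_gte(mean_relatedness(ids, sim$pedigree), 0)
})

test_that("ancestry contributions: conservation and self-contribution", {
  sim <- tiny_genetic_sim()
  et <- sim$schedule$event_times
  desc <- sim$samples$ancestry
  for (id in desc$ids) {
    for (slice in c(et[1] - 50L, et[4] + 50L)) {
      ac <- ancestry_contributions(sim, id, slice)
      expect_equal(sum(ac$fraction), 1, tolerance = 1e-9)
      expect_true(all(ac$fraction > 0))
      # ancestors were alive at the slice
      alive <- alive_at(sim$pedigree, slice)
      expect_true(all(ac$ancestor_id %in% alive))
    }
    # slice at the descendant's own sampling time: everything is its own
    ac_self <- ancestry_contributions(sim, id, desc$timestep)
    expect_equal(ac_self$ancestor_id, id)
    expect_equal(ac_self$fraction, 1)
  }
  expect_error(ancestry_contributions(sim, desc$ids[1],
                                      sim$tracking$track_from - 10),
               "recording window")
})

test_that("ancestry clouds: per-slice conservation and positive dispersion", {
  sim <- tiny_genetic_sim()
  cl <- ancestry_cloud(sim)
  expect_true(all(c("descendant_id", "slice", "ancestor_id", "fraction",
                    "x", "y") %in% names(cl)))
  tot <- stats::aggregate(fraction ~ descendant_id + slice, cl, sum)
  expect_equal(tot$fraction, rep(1, nrow(tot)), tolerance = 1e-9)
  before <- cl[cl$slice == "before", ]
  expect_gt(cloud_dispersion(before), 0)
})
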