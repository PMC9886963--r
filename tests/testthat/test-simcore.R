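test_that("seeded runs are bit-reproducible; seeds matter", {
  p <- sim_params(burn_in = 60, genetics_burn_in = 20, post_run = 20,
                  genome_length = 1e6, mu = 1e-5, rec = 1e-6, theta = 1e-3)
  a <- suppressWarnings(simulate_range("shrinkage", p, seed = 21, nx = 8, ny = 8))
  b <- suppressWarnings(simulate_range("shrinkage", p, seed = 21, nx = 8, ny = 8))
  d <- suppressWarnings(simulate_range("shrinkage", p, seed = 22, nx = 8, ny = 8))
  expect_identical(a$ts, b$ts)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$samples$final$hap1, b$samples$final$hap1)
  expect_false(identical(a$ts, d$ts))
})

test_that("demographic equilibrium on an uncontracted grid", {
  sim <- equilibrium_sim()
  ts <- sim$ts
  late <- ts$timestep > 150
  # long-run N within 15% of K * n_cells = 2000
  expect_lt(abs(mean(ts$N[late]) - 2000) / 2000, 0.15)
  # mean age within 25% of L = 4
  expect_lt(abs(mean(ts$mean_age[late]) - 4) / 4, 0.25)
  # no systematic N trend once equilibrated
  tf <- trend_fit(ts$timestep[late], ts$N[late])
  expect_lt(abs(tf$slope) * 150, 0.1 * mean(ts$N[late]))
  # absorbing boundaries kill some dispersers every few steps
  expect_gt(sum(ts$boundary_deaths), 0)
})

test_that("natal dispersal displacement has scale sigma; positions stay inside", {
  sim <- equilibrium_sim()
  expect_true(all(sim$final$x >= 0 & sim$final$x <= 20 &
                  sim$final$y >= 0 & sim$final$y <= 20))
  ped <- sim$pedigree
  kids <- ped[!is.na(ped$parent1) & ped$x > 3 & ped$x < 17 &
                ped$y > 3 & ped$y < 17, ]
  kids <- kids[seq_len(min(nrow(kids), 4000)), ]
  dx <- kids$x - ped$x[kids$parent1]      # birth coords of focal parent
  # per-axis displacement: mean 0, sd sigma (boundary truncation is mild
  # away from the edges)
  expect_lt(abs(mean(dx)), 0.05)
  expect_equal(stats::sd(dx), sim$params$sigma, tolerance = 0.15)
  # lineage spread grows with pedigree depth (random-walk accumulation)
  gp <- ped$parent1[kids$parent1]
  ok <- !is.na(gp)
  d1 <- abs(kids$x - ped$x[kids$parent1])[ok]
  d2 <- abs(kids$x[ok] - ped$x[gp[ok]])
  expect_gt(mean(d2), mean(d1))
})

test_that("population decline scales with habitable area removed", {
  # single small-scale contraction: decline fraction tracks removed area
  p <- sim_params(burn_in = 120, genetics_burn_in = 0, post_run = 150)
  s <- contraction_schedule("shrinkage", nx = 10, ny = 10, n_events = 2,
                            frac_per_event = 0.3, interval = 30, start = 120)
  sim <- simulate_range(s, p, seed = 13, genetics = FALSE,
                        region_samples = FALSE)
  sm <- summary(sim)
  # 60% of area at fitness 0.1 -> expected decline ~ 0.6 * (1 - 0.1) = 54%
  # plus sparse-zone attrition; direction and rough scale only
  expect_gt(sm$decline_pct, 35)
  expect_lt(sm$decline_pct, 80)
})

test_that("an uninhabitable landscape drives the population extinct", {
  # sigma large enough that every pair interacts: survival collapses for all
  s <- contraction_schedule("shrinkage", nx = 4, ny = 4, n_events = 1,
                            frac_per_event = 1, interval = 10, start = 60,
                            contracted_fitness = 1e-4)
  p <- sim_params(sigma = 2, burn_in = 60, genetics_burn_in = 0, post_run = 300)
  sim <- suppressWarnings(
    simulate_range(s, p, seed = 2, genetics = FALSE, region_samples = FALSE))
  expect_true(sim$extinct)
  expect_lt(sim$extinction_time, sim$n_steps)
  # partial outputs preserved up to the extinction timestep
  expect_equal(max(sim$ts$timestep), sim$extinction_time)
  expect_equal(sim$ts$N[nrow(sim$ts)], 0L)
})

test_that("offspring tallies are non-decreasing and recorded", {
  sim <- equilibrium_sim()
  expect_true(all(sim$final$offspring >= 0))
  expect_gt(mean(sim$final$offspring), 0)
  # every parent id in the pedigree was born before its offspring
  ped <- sim$pedigree
  has_p <- !is.na(ped$parent1)
  expect_true(all(ped$birth[ped$parent1[has_p]] < ped$birth[has_p]))
  expect_true(all(ped$birth[ped$parent2[has_p]] < ped$birth[has_p]))
})
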