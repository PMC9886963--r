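test_that("grid construction and validation", {
  g <- fitness_grid(20, 20)
  expect_equal(dim(g$values), c(20, 20))
  expect_true(all(g$values == 1.0))
  expect_equal(c(g$width, g$height), c(20, 20))

  expect_equal(length(fitness_grid(2, 2)$values), 4L)
  expect_true(all(fitness_grid(20, 20, 0.1)$values == 0.1))

  expect_error(fitness_grid(1, 20), "dimensions")
  expect_error(fitness_grid(20, 20, 0), "init_fitness")
  expect_error(fitness_grid(20, 20, 1.5), "init_fitness")
})

test_that("bilinear interpolation is exact at centers, bounded, continuous", {
  g <- apply_contraction(fitness_grid(20, 20), 1L)  # cell (1,1) -> 0.1
  # cell centers
  expect_equal(habitat_fitness(g, 0.5, 0.5), 0.1)
  expect_equal(habitat_fitness(g, 9.5, 9.5), 1.0)
  # midpoint between adjacent centers with h = 0.1 and 1.0
  expect_equal(habitat_fitness(g, 1.0, 0.5), 0.55)
  # bounded by extrema everywhere
  set.seed(1)
  x <- runif(500, 0, 20); y <- runif(500, 0, 20)
  v <- habitat_fitness(g, x, y)
  expect_true(all(v >= 0.1 - 1e-12 & v <= 1 + 1e-12))
  # continuity: tiny coordinate change, tiny value change
  expect_lt(abs(habitat_fitness(g, 1.2, 0.7) -
                habitat_fitness(g, 1.2 + 1e-7, 0.7 + 1e-7)), 1e-5)
  expect_error(habitat_fitness(g, -0.1, 5), "outside")
  expect_error(habitat_fitness(g, 5, 20.1), "outside")
})

test_that("contraction schedules have the published area fractions", {
  for (pat in c("shrinkage", "amputation", "fragmentation")) {
    s <- contraction_schedule(pat, start = 500)
    expect_equal(lengths(s$events), rep(88L, 4))
    cells <- unlist(s$events)
    expect_equal(anyDuplicated(cells), 0L)
    expect_equal(length(cells), 352L)         # 88% of 400
    expect_equal(diff(s$event_times), rep(100L, 3))
  }
  # no-contraction control
  s0 <- contraction_schedule("none")
  expect_length(s0$events, 0L)
  # seeded determinism of the random variant
  r1 <- contraction_schedule("random_fragmentation", start = 1, seed = 9)
  r2 <- contraction_schedule("random_fragmentation", start = 1, seed = 9)
  r3 <- contraction_schedule("random_fragmentation", start = 1, seed = 10)
  expect_identical(r1$events, r2$events)
  expect_false(identical(r1$events, r3$events))

  expect_error(contraction_schedule("melting"), "arg")
  expect_error(contraction_schedule("shrinkage", n_events = 5,
                                    frac_per_event = 0.25), "exceed")
})

test_that("remnant geometry per pattern", {
  # shrinkage: one contiguous centered block
  gs <- schedule_grid(contraction_schedule("shrinkage", start = 1))
  comp <- habitable_components(gs)
  expect_equal(max(comp), 1L)
  left <- which(comp == 1L, arr.ind = TRUE)
  expect_equal(nrow(left), 48L)
  expect_equal(mean(range(left[, 1])), 10.5, tolerance = 0.1)  # centered in x
  expect_equal(mean(range(left[, 2])), 10.5, tolerance = 0.1)  # centered in y

  # amputation: one contiguous block hugging the far (right) edge
  ga <- schedule_grid(contraction_schedule("amputation", start = 1))
  compa <- habitable_components(ga)
  expect_equal(max(compa), 1L)
  lefta <- which(compa == 1L, arr.ind = TRUE)
  expect_equal(nrow(lefta), 48L)
  expect_true(all(lefta[, 1] >= 18L))
  expect_true(any(lefta[, 1] == 20L))

  # fragmentation: several disjoint patches, none in the range center
  gf <- schedule_grid(contraction_schedule("fragmentation", start = 1))
  compf <- habitable_components(gf)
  expect_gte(max(compf), 2L)
  leftf <- which(compf > 0L, arr.ind = TRUE)
  expect_equal(nrow(leftf), 48L)
  center <- leftf[, 1] >= 9 & leftf[, 1] <= 12 & leftf[, 2] >= 9 & leftf[, 2] <= 12
  expect_equal(sum(center), 0L)
})

test_that("cumulative removal tracks k * frac_per_event within one cell", {
  s <- contraction_schedule("shrinkage", start = 1)
  for (k in 1:4) {
    removed <- sum(lengths(s$events[seq_len(k)]))
    expect_lte(abs(removed - k * 0.22 * 400), 1)
  }
})

test_that("apply_contraction changes exactly the listed cells", {
  g <- fitness_grid(20, 20)
  ev <- contraction_schedule("amputation", start = 1)$events[[1]]
  g2 <- apply_contraction(g, ev)
  expect_equal(sum(g2$values == 0.1), 88L)
  expect_equal(sum(g2$values == 1.0), 312L)
  expect_identical(apply_contraction(g, integer(0)), g)
  expect_error(apply_contraction(g, 401L), "outside")
})

test_that("schedule YAML round-trip and grid snapshots", {
  s <- contraction_schedule("fragmentation", start = 700)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_schedule_yaml(s, f)
  s2 <- read_schedule_yaml(f)
  expect_identical(s2$events, s$events)
  expect_identical(s2$event_times, s$event_times)

  d <- withr::local_tempdir()
  paths <- write_grid_snapshots(s, d)
  expect_length(paths, 5L)      # pre + 4 events
  m <- as.matrix(utils::read.table(paths[5], sep = "\t"))
  expect_equal(dim(m), c(20L, 20L))
  expect_equal(sum(m == 0.1), 352L)
})
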