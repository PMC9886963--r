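test_that("kernel maximum and truncated Gaussian shape", {
  expect_equal(kernel_max(1), 1 / (2 * pi))
  expect_equal(kernel_max(0.5), 1 / (2 * pi * 0.25))
  # normalization identity for arbitrary sigma
  for (s in c(0.2, 0.5, 1, 3)) expect_equal(kernel_max(s) * 2 * pi * s^2, 1)
  expect_error(kernel_max(0), "sigma")

  s <- 0.7
  m <- kernel_max(s)
  expect_equal(interaction_strength(0, s), m)
  expect_equal(interaction_strength(s, s), m * exp(-0.5))
  expect_identical(interaction_strength(3 * s, s), 0)      # hard truncation
  expect_identical(interaction_strength(10 * s, s), 0)
  d <- seq(0, 3 * s, length.out = 50)
  expect_true(all(diff(interaction_strength(d, s)) <= 0))  # monotone decreasing
  expect_true(all(interaction_strength(d, s) >= 0))
  expect_error(interaction_strength(-1, s), ">= 0")
})

test_that("clipped interaction area: closed form vs symmetry and Monte Carlo", {
  rect <- c(0, 0, 10, 10)
  expect_equal(clipped_interaction_area(5, 5, 1, rect), pi)          # interior
  expect_equal(clipped_interaction_area(0, 0, 1, rect), pi / 4)      # corner
  expect_equal(clipped_interaction_area(5, 0, 1, rect), pi / 2)      # edge
  expect_equal(clipped_interaction_area(0, 5, 2, rect), 2 * pi)      # edge, R=2

  # Monte-Carlo rejection-sampling oracle on random configurations
  set.seed(42)
  for (i in 1:20) {
    cx <- runif(1, 0, 20); cy <- runif(1, 0, 20); R <- runif(1, 0.3, 5)
    a <- clipped_interaction_area(cx, cy, R, c(0, 0, 20, 20))
    px <- runif(3e5, cx - R, cx + R); py <- runif(3e5, cy - R, cy + R)
    hit <- (px - cx)^2 + (py - cy)^2 <= R^2 &
      px >= 0 & px <= 20 & py >= 0 & py <= 20
    mc <- mean(hit) * (2 * R)^2
    expect_lt(abs(a - mc) / a, 0.005)
  }
  expect_error(clipped_interaction_area(1, 1, 0, rect), "radius")
  expect_error(clipped_interaction_area(1, 1, 1, c(0, 0, 0, 5)), "extent")
})

test_that("competition load: kernel sum with edge-area correction", {
  rect <- c(0, 0, 20, 20)
  m <- kernel_max(0.5)
  # isolated individual
  expect_equal(competition_load(10, 10, 0.5, rect), 0)
  # two coincident interior individuals: each feels exactly m
  expect_equal(competition_load(c(10, 10), c(10, 10), 0.5, rect), c(m, m))
  # the same pair at a corner: area correction of exactly 4
  expect_equal(competition_load(c(0, 0), c(0, 0), 0.5, rect), c(4 * m, 4 * m))
  # neighbours beyond 3*sigma do not compete
  expect_equal(competition_load(c(5, 7), c(5, 5), 0.5, rect), c(0, 0))
})

test_that("survival fitness follows W = 1 / (1 + rho C / h)", {
  expect_equal(competition_constant(0.25, 5), 0.04)
  expect_equal(survival_fitness(0, 1, 0.04), 1)
  expect_equal(survival_fitness(6.25, 1, 0.04), 0.8)
  # contraction lowers survival at fixed density
  expect_lt(survival_fitness(3, 0.1, 0.04), survival_fitness(3, 1.0, 0.04))
  # always a probability
  set.seed(7)
  W <- survival_fitness(runif(1000, 0, 100), runif(1000, 0.01, 1), 0.04)
  expect_true(all(W >= 0 & W <= 1))
  expect_error(survival_fitness(-1, 1, 0.04), ">= 0")
  expect_error(survival_fitness(1, 0, 0.04), "> 0")
})
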