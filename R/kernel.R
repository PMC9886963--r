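#' Gaussian interaction kernel
#'
#' Distances between individuals are converted into interaction strengths
#' (used both for spatial competition and for mate choice) by a Gaussian
#' kernel with maximum \eqn{m = 1 / (2 \pi \sigma^2)} at distance zero and a
#' hard truncation at \eqn{3\sigma}, beyond which competition and mating
#' probability are both exactly zero.
#'
#' @param sigma Kernel scale (= natal dispersal standard deviation), in
#'   distance units (cell sides).
#' @return \code{kernel_max}: the kernel value at distance zero.
#' @examples
#' kernel_max(1)                      # 1 / (2*pi)
#' interaction_strength(0.5, 0.5)     # m * exp(-1/2)
#' @export
kernel_max <- function(sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) stop("sigma must be > 0")
  1 / (2 * pi * sigma^2)
}

#' @rdname kernel_max
#' @param d Distance(s), >= 0.
#' @return \code{interaction_strength}: kernel value at distance \code{d},
#'   zero at and beyond \code{3 * sigma}.
#' @export
interaction_strength <- function(d, sigma) {
  if (!is.numeric(d) || any(d < 0)) stop("distances must be >= 0")
  m <- kernel_max(sigma)
  ifelse(d >= 3 * sigma, 0, m * exp(-d^2 / (2 * sigma^2)))
}

#' Edge-corrected interaction area
#'
#' Exact area of the intersection of the interaction disc with the range
#' rectangle (closed-form circle-rectangle intersection). Individuals near a
#' range edge have part of their interaction circle outside occupiable space;
#' the competition load is rescaled by full-disc area / clipped area so that
#' perceived density reflects the space actually available.
#'
#' @param x,y Disc center coordinates (vectorized).
#' @param radius Disc radius (> 0); the engine uses \code{3 * sigma}.
#' @param range_rect Numeric vector \code{c(x0, y0, x1, y1)}.
#' @return Numeric vector of intersection areas.
#' @examples
#' clipped_interaction_area(0, 0, 1, c(0, 0, 10, 10))   # quarter disc
#' @export
clipped_interaction_area <- function(x, y, radius, range_rect) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  r <- as.numeric(range_rect)
  if (length(r) != 4 || r[3] <= r[1] || r[4] <= r[2])
    stop("range_rect must be c(x0, y0, x1, y1) with positive extent")
  n <- max(length(x), length(y))
  cpp_circle_rect_area(rep_len(as.numeric(x), n), rep_len(as.numeric(y), n),
                       radius, r[1], r[2], r[3], r[4])
}

#' Edge-corrected competition load
#'
#' For each individual, the sum of interaction strengths to all neighbours
#' within \code{3 * sigma}, multiplied by the edge-correction factor
#' (full interaction-disc area over the area clipped to the range rectangle).
#' The focal individual is excluded from its own sum.
#'
#' @param x,y Coordinates of all individuals.
#' @param sigma Kernel scale.
#' @param range_rect Numeric vector \code{c(x0, y0, x1, y1)}.
#' @return Numeric vector of competition loads, one per individual.
#' @export
competition_load <- function(x, y, sigma, range_rect) {
  stopifnot(length(x) == length(y))
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  r <- as.numeric(range_rect)
  if (length(r) != 4 || r[3] <= r[1] || r[4] <= r[2])
    stop("range_rect must be c(x0, y0, x1, y1) with positive extent")
  cpp_competition_loads(as.numeric(x), as.numeric(y), sigma,
                        r[1], r[2], r[3], r[4])
}

#' Spatial competition constant
#'
#' \eqn{\rho = \lambda / ((1 + \lambda) K)}, where \eqn{\lambda = 1/L} is the
#' per-pair Poisson fecundity and K the per-cell carrying capacity. At this
#' value the density-dependent survival \code{\link{survival_fitness}}
#' balances fecundity at density K, so K is the demographic equilibrium.
#'
#' @param lambda Fecundity (mean offspring per mating pair per timestep).
#' @param K Carrying capacity per cell (one cell = one square distance unit).
#' @return The competition constant rho.
#' @examples
#' competition_constant(0.25, 5)   # 0.04
#' @export
competition_constant <- function(lambda, K) {
  if (lambda <= 0 || K <= 0) stop("lambda and K must be > 0")
  lambda / ((1 + lambda) * K)
}

#' Density-dependent survival
#'
#' Per-timestep survival probability of an individual with competition load
#' \code{C} on habitat of fitness \code{h}:
#' \deqn{W = \frac{1}{1 + \rho C / h}.}
#' Contraction acts by lowering h (to 0.1 in contracted cells), which lowers
#' survival at any given density.
#'
#' @param C Competition load(s), >= 0 (see \code{\link{competition_load}}).
#' @param h Habitat fitness in (0, 1].
#' @param rho Spatial competition constant (see
#'   \code{\link{competition_constant}}).
#' @return Survival probability in [0, 1].
#' @export
survival_fitness <- function(C, h, rho) {
  if (any(C < 0)) stop("competition load must be >= 0")
  if (any(h <= 0)) stop("habitat fitness must be > 0")
  pmin(1, pmax(0, 1 / (1 + rho * C / h)))
}
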