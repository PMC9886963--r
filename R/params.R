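#' Simulation parameters
#'
#' Collects the demographic and genetic parameters of the individual-based
#' model. Two scale profiles are provided: \code{"desk"} (the default;
#' genome of 1e7 bp with mutation rate 1e-6 and recombination rate 1e-7,
#' which preserves the per-gamete means of ~10 new mutations and ~1 crossover
#' at 1\% of the bookkeeping cost, a 500-timestep burn-in with
#' founder-diversity injection 200 timesteps before its end, and 3 replicates)
#' and \code{"paper"} (genome 1e9 bp, mutation rate 1e-8, recombination rate
#' 1e-9, 20,000-timestep burn-in, 10 replicates; intended for cluster use).
#'
#' Derived quantities are fixed by construction: fecundity
#' \code{lambda = 1/L} and the competition constant
#' \code{rho = lambda / ((1 + lambda) * K)}.
#'
#' The founder-injection diversity \code{theta} (expected pairwise difference
#' per site between two founder haplotypes) is the level a coalescent
#' completion of the burn-in would give. \code{theta = NULL} resolves at run
#' time to the census mutation-drift equilibrium \code{4 * K * nx * ny * mu}
#' of the landscape; the desk profile fixes it at \code{4e-3}, the
#' equilibrium for an effective size of about half the census (reproductive
#' variance and spatial structure put the realized effective size below the
#' census count, and the relative-diversity statistics are insensitive to
#' the injected level).
#'
#' @param profile \code{"desk"} or \code{"paper"}.
#' @param sigma Dispersal / interaction kernel scale, in cell sides.
#' @param K Carrying capacity per cell.
#' @param L Mean age in timesteps; fecundity is \code{1/L}.
#' @param genome_length Haploid genome length in base pairs.
#' @param mu Per-bp per-gamete mutation rate.
#' @param rec Per-bp per-gamete recombination rate.
#' @param burn_in Timesteps before the first contraction event.
#' @param genetics_burn_in Timesteps of genetic settling between
#'   founder-diversity injection and the end of the burn-in.
#' @param post_run Timesteps simulated after the final contraction event.
#' @param theta Founder-injection diversity per site, or \code{NULL} for the
#'   census-equilibrium default.
#' @param n_replicates Default replicate count for experiments.
#' @return An object of class \code{sim_params} (a validated list).
#' @examples
#' p <- sim_params()
#' p$rho                      # 0.04
#' p$genome_length * p$mu     # 10 new mutations per gamete
#' @export
sim_params <- function(profile = c("desk", "paper"),
                       sigma = 0.5, K = 5, L = 4,
                       genome_length = NULL, mu = NULL, rec = NULL,
                       burn_in = NULL, genetics_burn_in = NULL,
                       post_run = 400, theta = NULL, n_replicates = NULL) {
  profile <- match.arg(profile)
  theta_given <- !missing(theta)
  def <- switch(profile,
    desk  = list(genome_length = 1e7, mu = 1e-6, rec = 1e-7,
                 burn_in = 1000L, genetics_burn_in = 800L, n_replicates = 3L,
                 theta = 4e-3),
    paper = list(genome_length = 1e9, mu = 1e-8, rec = 1e-9,
                 burn_in = 20000L, genetics_burn_in = 2000L, n_replicates = 10L,
                 theta = NULL))
  genome_length <- if (is.null(genome_length)) def$genome_length else genome_length
  mu <- if (is.null(mu)) def$mu else mu
  rec <- if (is.null(rec)) def$rec else rec
  burn_in <- as.integer(if (is.null(burn_in)) def$burn_in else burn_in)
  genetics_burn_in <- as.integer(
    if (is.null(genetics_burn_in)) min(def$genetics_burn_in, burn_in) else genetics_burn_in)
  n_replicates <- as.integer(if (is.null(n_replicates)) def$n_replicates else n_replicates)
  if (!theta_given) theta <- def$theta

  if (sigma <= 0) stop("sigma must be > 0")
  if (K <= 0) stop("K must be > 0")
  if (L <= 0) stop("L must be > 0")
  if (genome_length <= 0) stop("genome_length must be > 0")
  if (mu < 0 || rec < 0) stop("rates must be >= 0")
  if (burn_in < 1L) stop("burn_in must be >= 1")
  if (genetics_burn_in < 0L || genetics_burn_in > burn_in)
    stop("genetics_burn_in must be in [0, burn_in]")
  if (post_run < 0) stop("post_run must be >= 0")
  if (!is.null(theta) && theta <= 0) stop("theta must be > 0 (or NULL)")

  lambda <- 1 / L
  structure(list(
    profile = profile, sigma = sigma, K = K, L = L,
    lambda = lambda, rho = competition_constant(lambda, K),
    genome_length = genome_length, mu = mu, rec = rec,
    burn_in = burn_in, genetics_burn_in = genetics_burn_in,
    post_run = as.integer(post_run), theta = theta,
    n_replicates = n_replicates), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> profile '%s'\n", x$profile))
  cat(sprintf("  sigma %.3g | K %g | L %g (lambda %.4g, rho %.4g)\n",
              x$sigma, x$K, x$L, x$lambda, x$rho))
  cat(sprintf("  genome %.3g bp | mu %.3g | rec %.3g (%.3g mutations, %.3g crossovers per gamete)\n",
              x$genome_length, x$mu, x$rec,
              x$genome_length * x$mu, x$genome_length * x$rec))
  cat(sprintf("  burn-in %d (injection at %d) | post-run %d | theta %s\n",
              x$burn_in, x$burn_in - x$genetics_burn_in, x$post_run,
              if (is.null(x$theta)) "census equilibrium (4*K*A*mu)" else format(x$theta)))
  invisible(x)
}

# resolve the default founder diversity for a given landscape
resolve_theta <- function(params, nx, ny) {
  if (!is.null(params$theta)) params$theta else 4 * params$K * nx * ny * params$mu
}
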