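#' Run one range-contraction simulation
#'
#' Executes burn-in, the scheduled contraction events, and the post-contraction
#' period of the individual-based model in a single seeded run. Within each
#' timestep the engine (in fixed order) applies any scheduled contraction,
#' lets every living individual attempt spatially explicit mate choice and
#' Poisson reproduction, disperses newborns (absorbing range boundaries),
#' applies density- and habitat-dependent survival
#' \eqn{W = 1/(1 + \rho C / h)} to adults and newborns alike, increments ages,
#' and records observables. Diploid genetics (founder-diversity injection,
#' infinite-sites mutation, recombination, founder-ancestry segments) is
#' activated \code{genetics_burn_in} timesteps before the end of the burn-in.
#'
#' @param pattern A pattern name accepted by \code{\link{contraction_schedule}},
#'   or a ready-made \code{contraction_schedule} object.
#' @param params A \code{\link{sim_params}} object.
#' @param seed Integer seed; the full run is reproducible from it.
#' @param nx,ny Grid dimensions (ignored when \code{pattern} is a schedule).
#' @param genetics Simulate genomes? Demography-only runs are much faster.
#' @param track_ancestry Record the gamete ancestry graph from 50 timesteps
#'   before the first event (needed for \code{\link{ancestry_cloud}});
#'   also schedules the 4-descendant ancestry sample.
#' @param region_samples Sample 50 individuals from each post-contraction
#'   region group (see \code{\link{region_groups}}) at the final timestep.
#' @param extra_samples Optional list of additional sample requests, each a
#'   list with elements \code{t}, \code{n}, \code{label}, and either
#'   \code{type = "random"} or \code{type = "cells"} plus \code{cells}.
#' @return An object of class \code{range_sim}: time series (\code{$ts}),
#'   pedigree log (\code{$pedigree}), genotype samples (\code{$samples}, a
#'   named list of \code{hap_sample} objects), final population
#'   (\code{$final}), the schedule, parameters, seeds, and (if requested)
#'   ancestry-tracking tables.
#' @examples
#' \donttest{
#' p <- sim_params(burn_in = 60, genetics_burn_in = 20, post_run = 40)
#' s <- simulate_range("shrinkage", p, seed = 1, nx = 8, ny = 8)
#' summary(s)
#' }
#' @export
simulate_range <- function(pattern = "none", params = sim_params(), seed = 1L,
                           nx = 20L, ny = 20L, genetics = TRUE,
                           track_ancestry = FALSE, region_samples = TRUE,
                           extra_samples = NULL) {
  stopifnot(inherits(params, "sim_params"))
  schedule <- if (inherits(pattern, "contraction_schedule")) {
    pattern
  } else {
    contraction_schedule(pattern, nx, ny, start = params$burn_in,
                         seed = if (identical(pattern, "random_fragmentation"))
                           as.integer(seed) else NULL)
  }
  nx <- schedule$nx; ny <- schedule$ny
  has_events <- length(schedule$events) > 0L
  t_first <- if (has_events) schedule$event_times[1L] else params$burn_in
  t_last <- if (has_events) schedule$event_times[length(schedule$event_times)] else params$burn_in
  if (genetics && has_events &&
      t_first < params$burn_in - params$genetics_burn_in)
    stop("first contraction event precedes genetic burn-in; increase start")
  n_steps <- t_last + params$post_run
  t_pre <- t_first - 50L
  if (t_pre < 1L && has_events)
    stop("burn-in too short for the pre-contraction sample")

  samples <- if (t_pre >= 1L) list(
    list(t = t_pre, n = 100L, type = "random", label = "pre", genotypes = TRUE),
    list(t = t_pre, n = 50L, type = "random", label = "ancient", genotypes = TRUE))
  else list()
  if (has_events) {
    for (e in seq_along(schedule$event_times))
      samples[[length(samples) + 1L]] <-
        list(t = schedule$event_times[e] + 50L, n = 100L, type = "random",
             label = paste0("post", e), genotypes = TRUE)
  }
  samples[[length(samples) + 1L]] <-
    list(t = n_steps, n = 100L, type = "random", label = "final", genotypes = TRUE)
  if (region_samples && schedule$pattern %in%
        c("shrinkage", "amputation", "fragmentation")) {
    rg <- region_groups(schedule$pattern, nx, ny)
    for (nm in names(rg))
      samples[[length(samples) + 1L]] <-
        list(t = n_steps, n = 50L, type = "cells", cells = rg[[nm]],
             label = nm, genotypes = TRUE)
  }
  if (track_ancestry)
    samples[[length(samples) + 1L]] <-
      list(t = min(t_last + 100L, n_steps), n = 4L, type = "random",
           label = "ancestry", genotypes = FALSE)
  for (sp in extra_samples) samples[[length(samples) + 1L]] <- sp
  samples <- lapply(samples, function(sp) {
    sp$type <- if (is.null(sp$type)) "random" else sp$type
    sp$genotypes <- if (is.null(sp$genotypes)) TRUE else sp$genotypes
    sp$t <- as.integer(sp$t); sp$n <- as.integer(sp$n)
    if (identical(sp$type, "cells")) sp$cells <- as.integer(sp$cells)
    sp
  })

  cfg <- list(
    grid_values = fitness_grid(nx, ny)$values,
    sigma = params$sigma, K = params$K, lambda = params$lambda,
    rho = params$rho, genome_length = params$genome_length,
    mu = params$mu, rec = params$rec,
    n_steps = as.integer(n_steps),
    genetics_start = if (genetics)
      as.integer(params$burn_in - params$genetics_burn_in) else -1L,
    theta = resolve_theta(params, nx, ny),
    track_from = if (track_ancestry) as.integer(t_pre) else -1L,
    event_times = as.integer(schedule$event_times),
    event_cells = schedule$events,
    contracted_fitness = schedule$contracted_fitness,
    samples = samples,
    sample_seed = as.numeric(seed) * 2654435761,
    init_n = as.integer(round(params$K * nx * ny)))

  set.seed(as.integer(seed))
  raw <- cpp_run_engine(cfg)

  got <- !vapply(raw$samples, is.null, logical(1))
  samp <- lapply(raw$samples[got], function(s) {
    structure(list(label = s$label, timestep = s$timestep,
                   requested_n = s$requested_n, ids = s$ids,
                   x = s$x, y = s$y, age = s$age,
                   arg1 = s$arg1, arg2 = s$arg2,
                   hap1 = s$hap1, hap2 = s$hap2),
              genome_length = params$genome_length, class = "hap_sample")
  })
  names(samp) <- vapply(samp, function(s) s$label, character(1))
  short <- vapply(samp, function(s) length(s$ids) < s$requested_n, logical(1))
  if (any(short))
    warning("sample shortfall (fewer living individuals than requested): ",
            paste(names(samp)[short], collapse = ", "))

  structure(list(
    ts = raw$ts, pedigree = raw$pedigree, samples = samp, final = raw$final,
    schedule = schedule, params = params, seed = as.integer(seed),
    n_steps = n_steps, extinct = raw$extinct,
    extinction_time = raw$extinction_time,
    tracking = raw$tracking,
    n_founder_haplotypes = raw$n_founder_haplotypes,
    n_pool_sites = raw$n_pool_sites), class = "range_sim")
}

#' @export
print.range_sim <- function(x, ...) {
  cat(sprintf("<range_sim> pattern '%s', %d timesteps, seed %d\n",
              x$schedule$pattern, x$n_steps, x$seed))
  nfin <- length(x$final$ids)
  cat(sprintf("  final N = %d%s; %d pedigree entries; samples: %s\n",
              nfin, if (x$extinct) " (EXTINCT)" else "",
              nrow(x$pedigree),
              if (length(x$samples)) paste(names(x$samples), collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
summary.range_sim <- function(object, ...) {
  ts <- object$ts
  has_events <- length(object$schedule$event_times) > 0L
  t_first <- if (has_events) object$schedule$event_times[1L] else NA_integer_
  pre_win <- if (has_events) ts$timestep < t_first & ts$timestep >= t_first - 100L
             else ts$timestep > object$params$burn_in - 100L
  post_win <- ts$timestep > object$n_steps - 50L
  out <- list(
    pattern = object$schedule$pattern,
    n_steps = object$n_steps,
    pre_N = mean(ts$N[pre_win]),
    post_N = mean(ts$N[post_win]),
    extinct = object$extinct)
  out$decline_pct <- if (has_events) 100 * (1 - out$post_N / out$pre_N) else NA_real_
  class(out) <- "summary.range_sim"
  out
}

#' @export
print.summary.range_sim <- function(x, ...) {
  cat(sprintf("range-contraction run ('%s')\n", x$pattern))
  cat(sprintf("  pre-contraction mean N : %.1f\n", x$pre_N))
  cat(sprintf("  final mean N           : %.1f\n", x$post_N))
  if (!is.na(x$decline_pct))
    cat(sprintf("  population decline     : %.1f%%\n", x$decline_pct))
  if (x$extinct) cat("  population went EXTINCT\n")
  invisible(x)
}

#' @export
plot.range_sim <- function(x, which = c("N", "mean_age", "mean_offspring"), ...) {
  which <- match.arg(which, c("N", "mean_age", "max_age", "mean_offspring"),
                     several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (w in which) {
    graphics::plot(x$ts$timestep, x$ts[[w]], type = "l", xlab = "timestep",
                   ylab = w, ...)
    graphics::abline(v = x$schedule$event_times, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' @export
print.hap_sample <- function(x, ...) {
  cat(sprintf("<hap_sample> '%s' at timestep %d: %d individuals%s\n",
              x$label, x$timestep, length(x$ids),
              if (is.null(x$hap1)) " (no genotypes)" else ""))
  invisible(x)
}

#' Individuals alive at a timestep
#'
#' @param pedigree Pedigree data frame from a \code{range_sim}.
#' @param t Timestep.
#' @return Integer vector of ids alive at the end of timestep \code{t}
#'   (born at or before \code{t}, died after \code{t} or still alive).
#' @export
alive_at <- function(pedigree, t) {
  ok <- pedigree$birth <= t & (is.na(pedigree$death) | pedigree$death > t)
  pedigree$id[ok]
}
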