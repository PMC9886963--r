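#' Post-contraction sampling regions
#'
#' Named groups of grid cells from which 50 individuals each are sampled in
#' the final generation, scenario by scenario: five groups including the
#' center for shrinkage (corner quadrants of the remnant block around a
#' central rectangle), four equal-height bands spanning the remnant strip for
#' amputation (top to lower), and the four remnant corner patches for
#' fragmentation (no habitable cells remain in the range center there). Each
#' group is compared against the random "ancient" pre-contraction sample.
#' Groups tile disjointly within the remnant area; extents are fixed
#' fractions of the remnant geometry, versioned here.
#'
#' @param scenario One of \code{"shrinkage"}, \code{"amputation"},
#'   \code{"fragmentation"}.
#' @param nx,ny Grid dimensions.
#' @return Named list of integer cell-id vectors.
#' @export
region_groups <- function(scenario, nx = 20L, ny = 20L) {
  scenario <- match.arg(scenario, c("shrinkage", "amputation", "fragmentation"))
  nx <- as.integer(nx); ny <- as.integer(ny)
  cell_id <- function(ix, iy) as.integer(outer(ix, (iy - 1L) * nx, `+`))
  if (scenario == "shrinkage") {
    b <- .shrink_block(nx, ny)
    cw <- max(2L, as.integer(round((b["x1"] - b["x0"] + 1L) / 2)))
    ch <- max(2L, as.integer(round((b["y1"] - b["y0"] + 1L) / 3)))
    cx <- (b["x0"] + b["x1"]) / 2; cy <- (b["y0"] + b["y1"]) / 2
    cxr <- as.integer(floor(cx - cw / 2 + 1L)):as.integer(floor(cx + cw / 2))
    cyr <- as.integer(floor(cy - ch / 2 + 1L)):as.integer(floor(cy + ch / 2))
    center <- cell_id(cxr, cyr)
    mx <- as.integer(floor(cx)); my <- as.integer(floor(cy))
    quad <- function(ix, iy) setdiff(cell_id(ix, iy), center)
    list(bottomleft = quad(b["x0"]:mx, b["y0"]:my),
         bottomright = quad((mx + 1L):b["x1"], b["y0"]:my),
         topleft = quad(b["x0"]:mx, (my + 1L):b["y1"]),
         topright = quad((mx + 1L):b["x1"], (my + 1L):b["y1"]),
         center = center)
  } else if (scenario == "amputation") {
    ord <- .order_amputation(nx, ny)
    n_removed <- as.integer(round(0.88 * nx * ny))
    remnant <- ord[(n_removed + 1L):(nx * ny)]
    iy_of <- ((remnant - 1L) %/% nx) + 1L
    qs <- as.integer(round(ny * c(1, 2, 3) / 4))
    list(lower = remnant[iy_of <= qs[1L]],
         lowermiddle = remnant[iy_of > qs[1L] & iy_of <= qs[2L]],
         uppermiddle = remnant[iy_of > qs[2L] & iy_of <= qs[3L]],
         top = remnant[iy_of > qs[3L]])
  } else {
    .frag_patches(nx, ny)
  }
}

#' Run the full contraction experiment
#'
#' Runs each scenario for \code{n_replicates} seeded replicates, computes the
#' per-run summaries (population decline, diversity per sampled group,
#' region-pair divergence and F_ST, relatedness trend), and aggregates across
#' replicates. Replicate seeds are derived deterministically from
#' \code{master_seed}; the whole result is reproducible from it. A replicate
#' that goes extinct is recorded and excluded from aggregates with a warning.
#'
#' @param scenarios Character vector of contraction patterns.
#' @param params A \code{\link{sim_params}}.
#' @param n_replicates Replicates per scenario (default from \code{params}).
#' @param master_seed Integer master seed.
#' @param genetics Simulate genomes (needed for diversity outputs).
#' @param relatedness Also compute the relatedness time series (pedigree
#'   kinship; moderate extra cost).
#' @param relatedness_cadence Timesteps between relatedness samples.
#' @param relatedness_replicates Replicate indices for which the relatedness
#'   series is computed (default: all).
#' @param keep_sims Keep the full \code{range_sim} objects (memory-heavy).
#' @return An object of class \code{range_experiment} with elements
#'   \code{runs} (per-run summaries), \code{diversity}, \code{fst},
#'   \code{decline}, \code{relatedness}, \code{params}, \code{master_seed}.
#' @export
run_experiment <- function(scenarios = c("shrinkage", "amputation", "fragmentation"),
                           params = sim_params(), n_replicates = NULL,
                           master_seed = 1L, genetics = TRUE,
                           relatedness = TRUE, relatedness_cadence = 25L,
                           relatedness_replicates = NULL, keep_sims = FALSE) {
  n_replicates <- if (is.null(n_replicates)) params$n_replicates
                  else as.integer(n_replicates)
  runs <- list(); diversity <- list(); fst <- list(); decl <- list(); rel <- list()
  sims <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[si]
    for (r in seq_len(n_replicates)) {
      seed <- as.integer(master_seed) + 10000L * si + r
      sim <- simulate_range(sc, params, seed = seed, genetics = genetics)
      sm <- summary(sim)
      run <- list(scenario = sc, replicate = r, seed = seed,
                  extinct = sim$extinct, pre_N = sm$pre_N, post_N = sm$post_N,
                  decline_pct = sm$decline_pct, ts = sim$ts)
      runs[[length(runs) + 1L]] <- run
      if (sim$extinct) {
        warning(sprintf("replicate %d of '%s' went extinct; excluded from aggregates",
                        r, sc))
        next
      }
      decl[[length(decl) + 1L]] <-
        data.frame(scenario = sc, replicate = r, pre_N = sm$pre_N,
                   post_N = sm$post_N, decline_pct = sm$decline_pct)
      if (genetics) {
        diversity[[length(diversity) + 1L]] <- diversity_table(sim, replicate = r)
        if (sc %in% c("shrinkage", "amputation", "fragmentation"))
          fst[[length(fst) + 1L]] <- fst_table(sim, replicate = r)
      }
      if (relatedness &&
          (is.null(relatedness_replicates) || r %in% relatedness_replicates)) {
        rs <- relatedness_series(sim, n = 50L,
                                 cadence = as.integer(relatedness_cadence),
                                 seed = seed + 1L)
        rs$scenario <- sc; rs$replicate <- r
        rel[[length(rel) + 1L]] <- rs
      }
      if (keep_sims) sims[[paste(sc, r, sep = "_")]] <- sim
      rm(sim); gc(FALSE)
    }
  }
  structure(list(
    runs = runs,
    decline = do.call(rbind, decl),
    diversity = if (length(diversity)) do.call(rbind, diversity) else NULL,
    fst = if (length(fst)) do.call(rbind, fst) else NULL,
    relatedness = if (length(rel)) do.call(rbind, rel) else NULL,
    sims = if (keep_sims) sims else NULL,
    scenarios = scenarios, n_replicates = n_replicates,
    params = params, master_seed = as.integer(master_seed)),
    class = "range_experiment")
}

#' @export
print.range_experiment <- function(x, ...) {
  cat(sprintf("<range_experiment> %s; %d replicate(s) each, master seed %d\n",
              paste(x$scenarios, collapse = ", "), x$n_replicates, x$master_seed))
  if (!is.null(x$decline)) {
    agg <- stats::aggregate(decline_pct ~ scenario, x$decline, mean)
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %-22s mean decline %.1f%%\n", agg$scenario[i],
                  agg$decline_pct[i]))
  }
  invisible(x)
}

#' Per-group diversity table for one run
#'
#' Group nucleotide diversity, mean individual heterozygosity, and the
#' individual-heterozygosity vectors (for rank tests) for every genotyped
#' sample of a run.
#'
#' @param sim A \code{range_sim} with genotyped samples.
#' @param replicate Replicate label attached to the rows.
#' @return Data frame with one row per sampled group; the per-individual
#'   heterozygosities are in the list column \code{ind_het}.
#' @export
diversity_table <- function(sim, replicate = 1L) {
  stopifnot(inherits(sim, "range_sim"))
  samp <- Filter(function(s) !is.null(s$hap1) && length(s$ids) >= 2L,
                 sim$samples)
  if (!length(samp)) stop("run has no genotyped samples")
  rows <- lapply(samp, function(s) {
    het <- individual_heterozygosity(s)
    data.frame(scenario = sim$schedule$pattern, replicate = replicate,
               label = s$label, timestep = s$timestep, n = length(s$ids),
               pi = nucleotide_diversity(s), mean_ind_het = mean(het))
  })
  out <- do.call(rbind, rows)
  out$ind_het <- unname(lapply(samp, individual_heterozygosity))
  rownames(out) <- NULL
  out
}

#' Region-pair divergence and F_ST table for one run
#'
#' All pairs among the scenario's region groups plus the pre-contraction
#' "ancient" group: within-group diversities, cross-group divergence
#' \eqn{\pi_{12}}, \eqn{F_{ST}}, and the geographic distance between group
#' sample centroids.
#'
#' @param sim A \code{range_sim} run with region samples.
#' @param replicate Replicate label attached to the rows.
#' @return Data frame, one row per group pair.
#' @export
fst_table <- function(sim, replicate = 1L) {
  stopifnot(inherits(sim, "range_sim"))
  rg <- names(region_groups(sim$schedule$pattern, sim$schedule$nx, sim$schedule$ny))
  labels <- c(rg[rg %in% names(sim$samples)], "ancient")
  labels <- labels[labels %in% names(sim$samples)]
  samp <- sim$samples[labels]
  usable <- vapply(samp, function(s) !is.null(s$hap1) && length(s$ids) >= 2,
                   logical(1))
  samp <- samp[usable]; labels <- labels[usable]
  if (length(samp) < 2L) stop("need at least two usable groups")
  piw <- vapply(samp, nucleotide_diversity, numeric(1))
  cx <- vapply(samp, function(s) mean(s$x), numeric(1))
  cy <- vapply(samp, function(s) mean(s$y), numeric(1))
  pairs <- utils::combn(seq_along(samp), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    p12 <- pairwise_divergence(samp[[i]], samp[[j]])
    data.frame(scenario = sim$schedule$pattern, replicate = replicate,
               group1 = labels[i], group2 = labels[j],
               pi1 = piw[i], pi2 = piw[j], pi12 = p12,
               fst = fst_nei(piw[i], piw[j], p12),
               distance = sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative-diversity timecourse
#'
#' Per scenario: mean group diversity at the pre-contraction sample, 50
#' timesteps after each event, and at the final timestep, divided by the same
#' replicate's own pre-contraction value, with a pairwise Wilcoxon rank-sum
#' comparison of individual heterozygosities against the pre-contraction
#' sample (pooled over replicates, Holm-adjusted within the post-vs-pre
#' family).
#'
#' The primary measure (\code{relative_diversity}) is the group mean of
#' individual heterozygosity: under spatially differentiated remnants it is
#' the measure that registers local diversity loss, whereas the pooled
#' pairwise diversity of a range-wide random sample (\code{relative_pi},
#' reported alongside) retains between-patch divergence and barely declines
#' even when every remnant patch has fixed a different set of lineages.
#'
#' @param experiment A \code{range_experiment} run with genetics.
#' @return Data frame with \code{scenario}, \code{label}, \code{timestep},
#'   \code{relative_diversity} (mean individual heterozygosity relative to
#'   pre-contraction), \code{relative_pi} (pooled sample diversity relative
#'   to pre-contraction), \code{n_replicates}, \code{p_vs_pre}.
#' @export
diversity_timecourse <- function(experiment) {
  stopifnot(inherits(experiment, "range_experiment"))
  dv <- experiment$diversity
  if (is.null(dv)) stop("experiment has no diversity tables (genetics off?)")
  dv <- dv[dv$label %in% c("pre", paste0("post", 1:9), "final"), ]
  out <- list()
  for (sc in unique(dv$scenario)) {
    d <- dv[dv$scenario == sc, ]
    pre <- d[d$label == "pre", ]
    rel <- d
    m <- match(d$replicate, pre$replicate)
    rel$relative_diversity <- d$mean_ind_het / pre$mean_ind_het[m]
    rel$relative_pi <- d$pi / pre$pi[m]
    for (lb in unique(d$label)) {
      sel <- rel[rel$label == lb, ]
      # pooled-replicate rank test of individual heterozygosity vs pre
      v_pre <- unlist(pre$ind_het)
      v_lb <- unlist(sel$ind_het)
      p <- if (lb == "pre") 1 else
        suppressWarnings(stats::wilcox.test(v_lb, v_pre)$p.value)
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, label = lb, timestep = sel$timestep[1L],
        relative_diversity = mean(sel$relative_diversity),
        relative_pi = mean(sel$relative_pi), n_replicates = nrow(sel),
        p_vs_pre = p)
    }
  }
  out <- do.call(rbind, out)
  fam <- out$label != "pre"
  out$p_vs_pre[fam] <- stats::p.adjust(out$p_vs_pre[fam], "holm")
  out[order(out$scenario, out$timestep), ]
}

#' Spatial ancestry clouds
#'
#' For each descendant in the run's ancestry sample, the locations of its
#' genetic ancestors at each time slice, weighted by their genomic
#' contribution. Default slices: 50 timesteps before the first contraction
#' event ("before") and 50 timesteps after the last one ("after").
#' Per-descendant fractions sum to 1 within each slice.
#'
#' @param sim A \code{range_sim} run with \code{track_ancestry = TRUE}.
#' @param slices Named integer vector of slice timesteps.
#' @return Data frame with \code{descendant_id}, \code{slice},
#'   \code{slice_time}, \code{ancestor_id}, \code{x}, \code{y},
#'   \code{fraction}.
#' @export
ancestry_cloud <- function(sim, slices = NULL) {
  stopifnot(inherits(sim, "range_sim"))
  if (is.null(sim$samples$ancestry)) stop("run has no ancestry sample")
  et <- sim$schedule$event_times
  if (is.null(slices)) {
    if (!length(et)) stop("default slices need a contraction schedule")
    slices <- c(before = et[1L] - 50L, after = et[length(et)] + 50L)
  }
  rows <- list()
  for (id in sim$samples$ancestry$ids) {
    for (k in seq_along(slices)) {
      ac <- ancestry_contributions(sim, id, slices[[k]])
      if (nrow(ac)) {
        ac$descendant_id <- id
        ac$slice <- names(slices)[k]
        ac$slice_time <- as.integer(slices[[k]])
        rows[[length(rows) + 1L]] <- ac
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("descendant_id", "slice", "slice_time", "ancestor_id", "x", "y",
          "fraction")]
}

#' Weighted dispersion of an ancestry cloud
#'
#' Contribution-weighted root-mean-square distance of ancestors from their
#' weighted centroid; large values mean ancestry spread across the range,
#' small values mean ancestry clustered (e.g. biased toward an extinction
#' front).
#'
#' @param cloud Rows of an \code{\link{ancestry_cloud}} data frame.
#' @return Scalar dispersion in distance units.
#' @export
cloud_dispersion <- function(cloud) {
  w <- cloud$fraction / sum(cloud$fraction)
  cx <- sum(w * cloud$x); cy <- sum(w * cloud$y)
  sqrt(sum(w * ((cloud$x - cx)^2 + (cloud$y - cy)^2)))
}
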