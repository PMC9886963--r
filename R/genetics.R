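#' Pedigree kinship and relatedness
#'
#' Malecot kinship computed from the recorded pedigree by the tabular method,
#' truncated at \code{max_depth} generations: ancestors beyond the truncation
#' depth are treated as unrelated, non-inbred founders. Inbreeding is ignored
#' in the recursion (diagonal kinship fixed at 1/2), so the relatedness matrix
#' \code{2 * kinship} has unit diagonal — the convention under which the
#' sample summary \eqn{F_r = (r - n)/n} (with r the sum of the matrix) is zero
#' for mutually unrelated individuals.
#'
#' @param ids Integer vector of individual ids.
#' @param pedigree Pedigree data frame (\code{id}, \code{parent1},
#'   \code{parent2}, \code{birth}, ...) from a \code{\link{simulate_range}} run.
#' @param max_depth Generations of pedigree to traverse (default 10;
#'   contributions beyond that are below 2^-10).
#' @return \code{kinship_matrix}: matrix of kinship coefficients (dimnames =
#'   ids). \code{kinship}: a single coefficient. \code{relatedness_matrix}:
#'   \code{2 * kinship_matrix}. \code{mean_relatedness}: the scalar F_r.
#' @examples
#' ped <- data.frame(id = 1:3, parent1 = c(NA, NA, 1), parent2 = c(NA, NA, 2),
#'                   birth = c(0, 0, 1))
#' kinship(1, 3, ped)            # parent-offspring: 0.25 (relatedness 0.5)
#' mean_relatedness(c(1, 3), ped)  # 0.5
#' @export
kinship_matrix <- function(ids, pedigree, max_depth = 10L) {
  ids <- as.integer(ids)
  if (any(!ids %in% pedigree$id)) stop("unknown individual id")
  maxid <- max(pedigree$id)
  p1 <- rep(NA_integer_, maxid); p2 <- rep(NA_integer_, maxid)
  birth <- rep(NA_integer_, maxid)
  p1[pedigree$id] <- pedigree$parent1
  p2[pedigree$id] <- pedigree$parent2
  birth[pedigree$id] <- pedigree$birth

  # ancestors within max_depth generations (minimum depth per individual)
  depth <- rep(NA_integer_, maxid)
  frontier <- unique(ids); depth[frontier] <- 0L
  d <- 0L
  while (length(frontier) && d < max_depth) {
    pa <- c(p1[frontier], p2[frontier])
    pa <- unique(pa[!is.na(pa)])
    pa <- pa[is.na(depth[pa])]
    depth[pa] <- d + 1L
    frontier <- pa
    d <- d + 1L
  }
  set <- which(!is.na(depth))
  set <- set[order(birth[set], set)]
  n <- length(set)
  pos <- rep(NA_integer_, maxid); pos[set] <- seq_len(n)
  trunc_founder <- depth[set] == max_depth  # parents outside the traversal

  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    phi[i, i] <- 0.5
    id <- set[i]
    if (trunc_founder[i]) next
    f <- p1[id]; m <- p2[id]
    fi <- if (!is.na(f)) pos[f] else NA_integer_
    mi <- if (!is.na(m)) pos[m] else NA_integer_
    if (is.na(fi) && is.na(mi)) next
    j <- seq_len(i - 1L)
    row <- numeric(i - 1L)
    if (!is.na(fi)) row <- row + 0.5 * phi[fi, j]
    if (!is.na(mi)) row <- row + 0.5 * phi[mi, j]
    phi[i, j] <- row
    phi[j, i] <- row
  }
  out <- phi[pos[ids], pos[ids], drop = FALSE]
  dimnames(out) <- list(ids, ids)
  out
}

#' @rdname kinship_matrix
#' @param a,b Individual ids.
#' @export
kinship <- function(a, b, pedigree, max_depth = 10L) {
  km <- kinship_matrix(c(a, b), pedigree, max_depth)
  km[1L, if (a == b) 1L else 2L]
}

#' @rdname kinship_matrix
#' @export
relatedness_matrix <- function(ids, pedigree, max_depth = 10L) {
  2 * kinship_matrix(ids, pedigree, max_depth)
}

#' @rdname kinship_matrix
#' @export
mean_relatedness <- function(ids, pedigree, max_depth = 10L) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 individuals")
  r <- sum(relatedness_matrix(ids, pedigree, max_depth))
  (r - n) / n
}

#' Average sampled relatedness through time
#'
#' Randomly samples \code{n} individuals alive at each queried timestep and
#' computes \eqn{F_r}. The sampling stream is independent of the simulation
#' stream, so the series can be re-drawn without re-simulating.
#'
#' @param sim A \code{range_sim}.
#' @param n Sample size per timestep (default 50).
#' @param cadence Sample every \code{cadence} timesteps.
#' @param from,to Timestep window (defaults: end of burn-in to end of run).
#' @param seed Seed for the sampling stream.
#' @param max_depth Pedigree truncation depth.
#' @return Data frame with \code{timestep}, \code{Fr}, \code{n}.
#' @export
relatedness_series <- function(sim, n = 50L, cadence = 10L, from = NULL,
                               to = NULL, seed = 1L, max_depth = 10L) {
  stopifnot(inherits(sim, "range_sim"))
  from <- if (is.null(from)) sim$params$burn_in - 50L else as.integer(from)
  to <- if (is.null(to)) sim$n_steps else as.integer(to)
  tt <- seq(from, to, by = as.integer(cadence))
  ped <- sim$pedigree
  out <- data.frame(timestep = tt, Fr = NA_real_, n = NA_integer_)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  for (k in seq_along(tt)) {
    ids <- alive_at(ped, tt[k])
    if (length(ids) < 2L) next
    take <- if (length(ids) > n) sample(ids, n) else ids
    out$Fr[k] <- mean_relatedness(take, ped, max_depth)
    out$n[k] <- length(take)
  }
  out
}

#' Gamete formation
#'
#' Draws gametes from a diploid parent given as two haplotype mutation lists:
#' Poisson(\code{rec * genome_length}) crossover breakpoints uniform on the
#' genome, alternate copying between the two haplotypes from a random
#' starting haplotype, plus Poisson(\code{mu * genome_length}) new unique
#' mutation positions. At the default parameters this gives ~1 crossover and
#' ~10 new mutations per gamete.
#'
#' @param hap1,hap2 Sorted numeric vectors of mutation positions.
#' @param params A \code{\link{sim_params}} (supplies genome length and rates).
#' @param n Number of gametes to draw.
#' @return List with \code{gametes} (list of sorted position vectors),
#'   \code{n_breakpoints}, \code{n_new_mutations}.
#' @export
make_gametes <- function(hap1, hap2, params = sim_params(), n = 1L) {
  stopifnot(inherits(params, "sim_params"))
  cpp_make_gametes(as.numeric(hap1), as.numeric(hap2),
                   params$genome_length, params$mu, params$rec, as.integer(n))
}

# ---- spatial ancestry -------------------------------------------------------

# record-range lookup: rows for a node are contiguous in creation order
.arg_rows <- function(tracking, node) {
  lo <- findInterval(node - 0.5, tracking$rec_hap) + 1L
  hi <- findInterval(node + 0.5, tracking$rec_hap)
  if (hi < lo) integer(0) else lo:hi
}

# project one haplotype (arg node id) onto the individuals alive at slice_time;
# returns named vector of genome lengths by ancestor id
.project_hap <- function(node, tracking, pedigree, slice_time, genome_length) {
  alive <- function(id) {
    b <- pedigree$birth[id]; d <- pedigree$death[id]
    b <= slice_time & (is.na(d) | d > slice_time)
  }
  acc <- new.env(parent = emptyenv())
  stack_l <- c(0); stack_r <- c(genome_length); stack_n <- c(node)
  while (length(stack_n)) {
    i <- length(stack_n)
    l <- stack_l[i]; r <- stack_r[i]; nd <- stack_n[i]
    stack_l <- stack_l[-i]; stack_r <- stack_r[-i]; stack_n <- stack_n[-i]
    owner <- tracking$owner[nd + 1L]
    if (alive(owner)) {
      key <- as.character(owner)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + (r - l)
      next
    }
    rows <- .arg_rows(tracking, nd)
    if (!length(rows))
      stop("ancestry recording does not reach slice time ", slice_time)
    rl <- tracking$rec_left[rows]; rr <- tracking$rec_right[rows]
    sr <- tracking$rec_src[rows]
    keep <- rl < r & rr > l
    if (any(keep)) {
      stack_l <- c(stack_l, pmax(rl[keep], l))
      stack_r <- c(stack_r, pmin(rr[keep], r))
      stack_n <- c(stack_n, sr[keep])
    }
  }
  ids <- as.integer(ls(acc))
  stats::setNames(vapply(as.character(ids), function(k) acc[[k]], numeric(1)), ids)
}

#' Genomic contributions of ancestors at a past time slice
#'
#' For a sampled descendant, computes the fraction of its diploid genome that
#' descends from each individual alive at \code{slice_time}, by projecting the
#' recorded gamete ancestry graph backward through recombination breakpoints.
#' Fractions over all ancestors sum to 1; a descendant alive at the slice
#' contributes (part of) its own genome to itself.
#'
#' @param sim A \code{range_sim} run with \code{track_ancestry = TRUE}.
#' @param descendant_id Id of a sampled descendant (from the \code{ancestry}
#'   sample or the final population).
#' @param slice_time Timestep of the slice; must be at or after the start of
#'   ancestry recording.
#' @return Data frame with \code{ancestor_id}, \code{fraction}, and the
#'   ancestor's (birth) coordinates \code{x}, \code{y}.
#' @export
ancestry_contributions <- function(sim, descendant_id, slice_time) {
  stopifnot(inherits(sim, "range_sim"))
  tr <- sim$tracking
  if (is.null(tr)) stop("run with track_ancestry = TRUE to record ancestry")
  if (slice_time < tr$track_from)
    stop("slice_time precedes the ancestry recording window")
  nodes <- NULL
  for (s in sim$samples) {
    k <- match(descendant_id, s$ids)
    if (!is.na(k) && !is.null(s$arg1) && s$arg1[k] >= 0) {
      nodes <- c(s$arg1[k], s$arg2[k]); break
    }
  }
  if (is.null(nodes)) {
    k <- match(descendant_id, tr$final_ids)
    if (!is.na(k)) nodes <- c(tr$final_h1[k], tr$final_h2[k])
  }
  if (is.null(nodes) || any(nodes < 0))
    stop("descendant not found in any tracked sample")
  L <- sim$params$genome_length
  a1 <- .project_hap(nodes[1], tr, sim$pedigree, slice_time, L)
  a2 <- .project_hap(nodes[2], tr, sim$pedigree, slice_time, L)
  ids <- sort(unique(c(as.integer(names(a1)), as.integer(names(a2)))))
  len <- vapply(as.character(ids), function(k) {
    (if (k %in% names(a1)) a1[[k]] else 0) + (if (k %in% names(a2)) a2[[k]] else 0)
  }, numeric(1))
  data.frame(ancestor_id = ids, fraction = len / (2 * L),
             x = sim$pedigree$x[ids], y = sim$pedigree$y[ids], row.names = NULL)
}
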