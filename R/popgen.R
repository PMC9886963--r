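#' @useDynLib rangesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# normalize input: a hap_sample, or a plain list of sorted position vectors
.as_haps <- function(x) {
  if (inherits(x, "hap_sample")) {
    if (is.null(x$hap1)) stop("sample carries no genotypes")
    c(x$hap1, x$hap2)
  } else if (is.list(x)) x
  else stop("expected a hap_sample or a list of haplotype position vectors")
}

.genome_length_of <- function(x, genome_length) {
  if (!is.null(genome_length)) return(genome_length)
  gl <- attr(x, "genome_length")
  if (is.null(gl)) stop("genome_length must be supplied")
  gl
}

#' Individual heterozygosity
#'
#' Per-site heterozygosity of each diploid: the number of positions carried by
#' exactly one of its two haplotypes, divided by genome length. This is the
#' "individual nucleotide diversity" mapped in the spatial-diversity figures.
#'
#' @param x A \code{hap_sample} (from \code{\link{simulate_range}} samples).
#' @param genome_length Genome length in bp (defaults to the sample's).
#' @return Numeric vector, one value per sampled individual.
#' @export
individual_heterozygosity <- function(x, genome_length = NULL) {
  stopifnot(inherits(x, "hap_sample"))
  if (is.null(x$hap1)) stop("sample carries no genotypes")
  L <- .genome_length_of(x, genome_length)
  n <- length(x$hap1)
  vapply(seq_len(n), function(i) {
    a <- x$hap1[[i]]; b <- x$hap2[[i]]
    (length(a) + length(b) - 2 * sum(a %in% b)) / L
  }, numeric(1))
}

#' Nucleotide diversity within a group
#'
#' Mean pairwise difference per site over haplotype pairs in the group. By
#' default all \code{choose(2n, 2)} haplotype pairs are used (the standard
#' sample estimator, including each individual's own two haplotypes);
#' \code{within_individual_pairs = FALSE} restricts to between-individual
#' pairs, which differs by O(1/n).
#'
#' @param x A \code{hap_sample} or a list of sorted mutation-position vectors.
#' @param genome_length Genome length in bp.
#' @param within_individual_pairs Include each individual's own haplotype pair?
#' @return Nucleotide diversity per site (a scalar).
#' @export
nucleotide_diversity <- function(x, genome_length = NULL,
                                 within_individual_pairs = TRUE) {
  haps <- .as_haps(x)
  L <- .genome_length_of(if (inherits(x, "hap_sample")) x else haps, genome_length)
  if (inherits(x, "hap_sample") && length(x$hap1) < 2L)
    stop("group size must be >= 2")
  if (length(haps) < 2L) stop("need at least 2 haplotypes")
  D <- cpp_pair_diff_matrix(haps)
  if (!within_individual_pairs) {
    if (!inherits(x, "hap_sample"))
      stop("within_individual_pairs = FALSE requires a hap_sample")
    n <- length(x$hap1)
    keep <- upper.tri(D)
    for (i in seq_len(n)) keep[i, i + n] <- FALSE
    mean(D[keep]) / L
  } else {
    mean(D[upper.tri(D)]) / L
  }
}

#' Pairwise divergence between two groups
#'
#' Mean per-site difference over all cross-group haplotype pairs
#' (\eqn{\pi_{12}}).
#'
#' @param g1,g2 \code{hap_sample}s or lists of haplotype position vectors.
#' @param genome_length Genome length in bp.
#' @return Pairwise divergence per site (a scalar).
#' @export
pairwise_divergence <- function(g1, g2, genome_length = NULL) {
  h1 <- .as_haps(g1); h2 <- .as_haps(g2)
  if (!length(h1) || !length(h2)) stop("both groups must be non-empty")
  L <- .genome_length_of(if (inherits(g1, "hap_sample")) g1 else h1, genome_length)
  D <- cpp_pair_diff_matrix(c(h1, h2))
  i <- seq_along(h1); j <- length(h1) + seq_along(h2)
  mean(D[i, j, drop = FALSE]) / L
}

#' F_ST from within- and between-group diversity
#'
#' The differentiation statistic
#' \deqn{F_{ST} = 1 - \frac{2(\pi_1 + \pi_2)}{\pi_1 + 2\pi_{12} + \pi_2},}
#' zero when there is no structure (\eqn{\pi_1 = \pi_2 = \pi_{12}}), one for
#' fixed differences, and possibly slightly negative by sampling (reported as
#' computed).
#'
#' @param pi1,pi2 Within-group nucleotide diversities (>= 0).
#' @param pi12 Between-group pairwise divergence (>= 0).
#' @return F_ST (vectorized). Zero denominators yield \code{NA} with a warning.
#' @examples
#' fst_nei(0.01, 0.01, 0.02)   # 1/3
#' @export
fst_nei <- function(pi1, pi2, pi12) {
  if (any(pi1 < 0 | pi2 < 0 | pi12 < 0)) stop("diversities must be >= 0")
  den <- pi1 + 2 * pi12 + pi2
  out <- 1 - 2 * (pi1 + pi2) / den
  if (any(den == 0)) {
    warning("zero denominator: F_ST undefined")
    out[den == 0] <- NA_real_
  }
  out
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper used to justify nonparametric group comparisons in reports.
#'
#' @param values Numeric sample (n >= 3, non-degenerate).
#' @return List with \code{statistic} and \code{p.value}.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Pairwise Wilcoxon rank-sum comparisons
#'
#' Unpaired rank-sum (Mann-Whitney) tests for all group pairs with Holm
#' adjustment by default (groups at different sampling points are different
#' individuals, so the unpaired test applies; both the pairing and the
#' adjustment are switches). Exact null distributions are used automatically
#' for small tie-free samples.
#'
#' @param values Numeric vector of statistic values (e.g. individual pi).
#' @param groups Group labels, same length as \code{values}.
#' @param adjust Multiple-testing adjustment (see \code{\link[stats]{p.adjust}}).
#' @param paired Use the signed-rank (paired) test instead.
#' @return Symmetric matrix of adjusted p-values with unit diagonal.
#' @export
pairwise_wilcoxon <- function(values, groups, adjust = "holm", paired = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  pt <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups, p.adjust.method = adjust,
                                paired = paired, exact = NULL))
  lev <- levels(groups)
  k <- length(lev)
  out <- matrix(1, k, k, dimnames = list(lev, lev))
  for (i in rownames(pt$p.value)) for (j in colnames(pt$p.value)) {
    p <- pt$p.value[i, j]
    if (!is.na(p)) { out[i, j] <- p; out[j, i] <- p }
  }
  out
}

#' Linear trend of a statistic over time
#'
#' Ordinary least-squares fit of a statistic on timestep, reporting the slope,
#' the coefficient of determination, and the slope p-value.
#'
#' @param timestep Numeric predictor (non-constant, >= 3 points).
#' @param value Response values.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value}.
#' @export
trend_fit <- function(timestep, value) {
  ok <- stats::complete.cases(timestep, value)
  timestep <- timestep[ok]; value <- value[ok]
  if (length(timestep) < 3L) stop("need at least 3 points")
  if (stats::sd(timestep) == 0) stop("timestep must not be constant")
  fit <- stats::lm(value ~ timestep)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate inputs
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2L, 4L]))
}
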