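#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates it fail-fast (unknown keys are
#' rejected by name), and resolves all defaults through
#' \code{\link{sim_params}}. A minimal configuration needs only a scenario
#' and a seed; everything else takes the model defaults (K = 5, L = 4, 4
#' events removing 22\% each, 100 timesteps apart, ...).
#'
#' @param path Path to a YAML file.
#' @return An object of class \code{run_config}: list with \code{scenario},
#'   \code{seed}, \code{nx}, \code{ny}, \code{params} (a \code{sim_params}),
#'   \code{genetics}, \code{track_ancestry}, \code{output_dir}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  param_keys <- c("profile", "sigma", "K", "L", "genome_length", "mu", "rec",
                  "burn_in", "genetics_burn_in", "post_run", "theta",
                  "n_replicates")
  top_keys <- c("scenario", "seed", "nx", "ny", "genetics", "track_ancestry",
                "output_dir")
  unknown <- setdiff(names(raw), c(param_keys, top_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  params <- do.call(sim_params, raw[intersect(names(raw), param_keys)])
  scenario <- if (is.null(raw$scenario)) "none" else raw$scenario
  scenario <- match.arg(scenario, c("shrinkage", "amputation", "fragmentation",
                                    "random_fragmentation", "none"))
  structure(list(
    scenario = scenario,
    seed = as.integer(if (is.null(raw$seed)) 1L else raw$seed),
    nx = as.integer(if (is.null(raw$nx)) 20L else raw$nx),
    ny = as.integer(if (is.null(raw$ny)) 20L else raw$ny),
    genetics = if (is.null(raw$genetics)) TRUE else isTRUE(raw$genetics),
    track_ancestry = isTRUE(raw$track_ancestry),
    output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir,
    params = params), class = "run_config")
}

#' @rdname load_config
#' @param config A \code{run_config}.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  out <- list(scenario = config$scenario, seed = config$seed,
              nx = config$nx, ny = config$ny,
              genetics = config$genetics,
              track_ancestry = config$track_ancestry,
              output_dir = config$output_dir,
              profile = p$profile, sigma = p$sigma, K = p$K, L = p$L,
              genome_length = p$genome_length, mu = p$mu, rec = p$rec,
              burn_in = p$burn_in, genetics_burn_in = p$genetics_burn_in,
              post_run = p$post_run, n_replicates = p$n_replicates)
  if (!is.null(p$theta)) out$theta <- p$theta
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> scenario '%s', seed %d, %dx%d grid, profile '%s'\n",
              x$scenario, x$seed, x$nx, x$ny, x$params$profile))
  invisible(x)
}

#' Write a genotype sample as VCF
#'
#' Writes a diploid, phased, GT-only VCF (one pseudo-chromosome "1"). The
#' continuous infinite-sites mutation positions are rounded to integer base
#' pairs; the rare collisions created by rounding are resolved by bumping to
#' the next free position so distinct sites stay distinct and all pairwise
#' genotype differences are preserved exactly.
#'
#' @param sample A genotyped \code{hap_sample}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(sample, path) {
  stopifnot(inherits(sample, "hap_sample"))
  if (is.null(sample$hap1)) stop("sample carries no genotypes")
  if (length(sample$ids) == 0L) stop("cannot write a VCF for an empty sample")
  haps <- c(sample$hap1, sample$hap2)
  sites <- sort(unique(as.numeric(unlist(haps))))
  pos <- as.integer(floor(sites)) + 1L
  if (length(pos) > 1L)                     # bump rounding collisions
    for (i in 2:length(pos)) if (pos[i] <= pos[i - 1L]) pos[i] <- pos[i - 1L] + 1L
  n <- length(sample$hap1)
  gt <- matrix("0|0", nrow = length(sites), ncol = n)
  for (i in seq_len(n)) {
    a <- !is.na(match(sites, sample$hap1[[i]]))
    b <- !is.na(match(sites, sample$hap2[[i]]))
    gt[, i] <- paste0(as.integer(a), "|", as.integer(b))
  }
  ind_names <- paste0("ind_", sample$ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=1,length=%d>",
            max(as.integer(attr(sample, "genome_length")), max(pos))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind_names), collapse = "\t")), con)
  body <- paste("1", pos, ".", "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read back a VCF written by \code{\link{write_vcf}}
#'
#' Minimal reader for the package's own VCF dialect (diploid phased GT-only
#' records); returns a \code{hap_sample} whose haplotypes carry the integer
#' site positions.
#'
#' @param path VCF file path.
#' @param genome_length Genome length to attach to the sample.
#' @return A \code{hap_sample}.
#' @export
read_vcf_sample <- function(path, genome_length) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("not a VCF file: ", path)
  cols <- strsplit(hdr, "\t")[[1L]]
  inds <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  pos <- vapply(fields, function(f) as.numeric(f[2L]), numeric(1))
  n <- length(inds)
  hap1 <- vector("list", n); hap2 <- vector("list", n)
  gts <- t(vapply(fields, function(f) f[10:(9 + n)], character(n)))
  if (n == 1L) gts <- matrix(gts, ncol = 1L)
  for (i in seq_len(n)) {
    a <- substr(gts[, i], 1L, 1L) == "1"
    b <- substr(gts[, i], 3L, 3L) == "1"
    hap1[[i]] <- pos[a]; hap2[[i]] <- pos[b]
  }
  ids <- as.integer(sub("^ind_", "", inds))
  structure(list(label = "vcf", timestep = NA_integer_, requested_n = n,
                 ids = ids, x = rep(NA_real_, n), y = rep(NA_real_, n),
                 age = rep(NA_integer_, n), arg1 = NULL, arg2 = NULL,
                 hap1 = hap1, hap2 = hap2),
            genome_length = genome_length, class = "hap_sample")
}

#' Persist the outputs of a run
#'
#' Writes the run's tables under \code{dir}: the per-timestep demography TSV,
#' the pedigree TSV, the final-population snapshot TSV, one VCF per genotyped
#' sample, diversity and F_ST CSVs where computable, the ancestry-cloud CSV
#' for tracked runs, and a JSON manifest (seed, parameters, file checksums).
#'
#' @param sim A \code{range_sim}.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "range_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wrote <- character(0)
  wt <- function(df, name, sep = "\t") {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = sep, row.names = FALSE, quote = FALSE)
    wrote <<- c(wrote, p)
    p
  }
  wt(sim$ts, "timeseries.tsv")
  wt(sim$pedigree, "pedigree.tsv")
  wt(as.data.frame(sim$final), "final_population.tsv")
  for (s in sim$samples) {
    if (is.null(s$hap1) || length(s$ids) == 0L) next
    p <- file.path(dir, sprintf("sample_%s.vcf", s$label))
    write_vcf(s, p)
    wrote <- c(wrote, p)
  }
  geno <- Filter(function(s) !is.null(s$hap1), sim$samples)
  if (length(geno)) {
    dv <- diversity_table(sim)
    dv$ind_het <- NULL
    wt(dv, "diversity.csv", sep = ",")
    if (sim$schedule$pattern %in% c("shrinkage", "amputation", "fragmentation") &&
        any(names(sim$samples) %in% names(region_groups(sim$schedule$pattern))))
      wt(fst_table(sim), "fst.csv", sep = ",")
  }
  if (!is.null(sim$tracking) && !is.null(sim$samples$ancestry))
    wt(ancestry_cloud(sim), "ancestry.csv", sep = ",")
  manifest <- list(
    package = "rangesim",
    version = as.character(utils::packageVersion("rangesim")),
    seed = sim$seed,
    pattern = sim$schedule$pattern,
    n_steps = sim$n_steps,
    extinct = sim$extinct,
    params = unclass(sim$params),
    files = lapply(stats::setNames(wrote, basename(wrote)),
                   function(p) list(md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
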