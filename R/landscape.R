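#' Habitat fitness grid
#'
#' Builds the discrete habitat-fitness landscape underlying the continuous
#' range. The range is a rectangle of \code{nx} by \code{ny} cells, one
#' distance unit per cell side, with the continuous origin at the lower-left
#' corner. Each cell carries a habitat-fitness value in (0, 1]; fitness at a
#' continuous coordinate is obtained by bilinear interpolation between cell
#' centers (see \code{\link{habitat_fitness}}).
#'
#' Cells are addressed either by index pair \code{(ix, iy)} (column
#' \code{ix} in \code{1..nx}, row \code{iy} in \code{1..ny}, cell
#' \code{(ix, iy)} covering the unit square \code{[ix-1, ix] x [iy-1, iy]})
#' or by the column-major linear id \code{ix + (iy - 1) * nx}, which is also
#' the linear index into the value matrix.
#'
#' @param nx,ny Number of cells along x and y (default 20 x 20).
#' @param init_fitness Initial habitat fitness for every cell, in (0, 1].
#' @return An object of class \code{fitness_grid}: a list with elements
#'   \code{values} (an \code{nx} x \code{ny} matrix), \code{nx}, \code{ny},
#'   \code{width}, \code{height}.
#' @examples
#' g <- fitness_grid(20, 20)
#' habitat_fitness(g, 10.2, 3.7)
#' @export
fitness_grid <- function(nx = 20L, ny = 20L, init_fitness = 1.0) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 2L || ny < 2L)
    stop("grid dimensions must be integers >= 2")
  if (!is.numeric(init_fitness) || length(init_fitness) != 1L ||
      init_fitness <= 0 || init_fitness > 1)
    stop("init_fitness must be a single value in (0, 1]")
  structure(
    list(values = matrix(init_fitness, nrow = nx, ncol = ny),
         nx = nx, ny = ny, width = as.numeric(nx), height = as.numeric(ny)),
    class = "fitness_grid")
}

#' @export
print.fitness_grid <- function(x, ...) {
  cat(sprintf("<fitness_grid> %d x %d cells (%g x %g distance units)\n",
              x$nx, x$ny, x$width, x$height))
  tab <- table(x$values)
  cat("  cell values:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.matrix.fitness_grid <- function(x, ...) x$values

#' Habitat fitness at continuous coordinates
#'
#' Bilinear interpolation of cell-center fitness values to a continuous
#' position. Values are exact at cell centers and continuous everywhere;
#' outside the outermost ring of cell centers the interpolation clamps to the
#' nearest center (constant extrapolation), so values are always bounded by
#' the cell-value extrema. Coordinates outside the range rectangle are an
#' error: the simulation treats such positions as death by dispersal.
#'
#' @param grid A \code{\link{fitness_grid}}.
#' @param x,y Coordinates (vectorized, recycled to common length).
#' @return Numeric vector of interpolated habitat fitness values.
#' @export
habitat_fitness <- function(grid, x, y) {
  stopifnot(inherits(grid, "fitness_grid"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  if (any(is.na(x) | is.na(y)))
    stop("coordinates must be non-missing")
  if (any(x < 0 | x > grid$width | y < 0 | y > grid$height))
    stop("coordinate outside the range rectangle")
  cpp_bilinear(grid$values, x, y)
}

#' Contraction schedules
#'
#' Generates the timed cell-removal schedule for one pattern of range
#' contraction. Each event lists the cells whose habitat fitness drops to
#' \code{contracted_fitness} (0.1 by default) at that timestep; events are
#' disjoint and spaced \code{interval} timesteps apart, and together remove
#' \code{round(n_events * frac_per_event * nx * ny)} cells (88\% of a 20 x 20
#' range at the defaults).
#'
#' Patterns:
#' \describe{
#'   \item{shrinkage}{periphery-to-core: the most peripheral cells (largest
#'     Chebyshev distance to a centered 8 x 6 remnant block) are removed
#'     first; the final 48 cells are the centered block.}
#'   \item{amputation}{an extinction front advancing from the left edge:
#'     cells are removed column by column; the remnant hugs the right edge
#'     and spans the full range height.}
#'   \item{fragmentation}{loss of continuity: cells are removed from the
#'     center outward, leaving four disjoint corner patches (two of 16 cells,
#'     two of 8) with no habitable cells in the range center.}
#'   \item{random_fragmentation}{cells drawn uniformly without replacement
#'     from the seeded generator.}
#'   \item{none}{empty schedule (control).}
#' }
#' All deterministic patterns are versioned in code; arbitrary geometries can
#' be supplied via \code{custom_events}.
#'
#' @param pattern One of \code{"shrinkage"}, \code{"amputation"},
#'   \code{"fragmentation"}, \code{"random_fragmentation"}, \code{"none"}.
#' @param nx,ny Grid dimensions.
#' @param n_events Number of discrete contraction events (default 4).
#' @param frac_per_event Fraction of all cells removed per event (default 0.22).
#' @param interval Timesteps between events (default 100).
#' @param start Timestep of the first event.
#' @param seed Integer seed, used only by \code{random_fragmentation}.
#' @param contracted_fitness Fitness value assigned to removed cells.
#' @param custom_events Optional list of integer cell-id vectors overriding
#'   the built-in geometry (must be disjoint, valid ids).
#' @return An object of class \code{contraction_schedule}: list with
#'   \code{pattern}, \code{event_times}, \code{events} (list of cell-id
#'   vectors), \code{nx}, \code{ny}, \code{contracted_fitness}.
#' @examples
#' s <- contraction_schedule("shrinkage", start = 500)
#' lengths(s$events)      # 88 cells per event
#' @export
contraction_schedule <- function(pattern, nx = 20L, ny = 20L, n_events = 4L,
                                 frac_per_event = 0.22, interval = 100L,
                                 start = 500L, seed = NULL,
                                 contracted_fitness = 0.1,
                                 custom_events = NULL) {
  pattern <- match.arg(pattern, c("shrinkage", "amputation", "fragmentation",
                                  "random_fragmentation", "none"))
  nx <- as.integer(nx); ny <- as.integer(ny)
  n_events <- as.integer(n_events)
  if (pattern == "none") n_events <- 0L
  if (n_events < 0L) stop("n_events must be >= 0")
  if (n_events * frac_per_event > 1 + 1e-12)
    stop("n_events * frac_per_event must not exceed 1")
  n_cells <- nx * ny
  n_remove_total <- as.integer(round(n_events * frac_per_event * n_cells))
  # distribute as evenly as whole cells allow
  per_event <- if (n_events > 0L)
    diff(round(seq(0L, n_remove_total, length.out = n_events + 1L))) else integer(0)

  events <- if (!is.null(custom_events)) {
    if (length(custom_events) != n_events)
      stop("custom_events must have one cell set per event")
    ev <- lapply(custom_events, function(e) sort(unique(as.integer(e))))
    all_cells <- unlist(ev)
    if (any(all_cells < 1L | all_cells > n_cells))
      stop("custom event cell id outside grid")
    if (anyDuplicated(all_cells)) stop("custom event cell sets must be disjoint")
    ev
  } else if (n_events == 0L) {
    list()
  } else {
    order_all <- switch(pattern,
      shrinkage = .order_shrinkage(nx, ny),
      amputation = .order_amputation(nx, ny),
      fragmentation = .order_fragmentation(nx, ny),
      random_fragmentation = {
        if (is.null(seed)) stop("random_fragmentation requires a seed")
        withr_seed <- function(expr) {  # local RNG scope
          old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
          on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
                  else assign(".Random.seed", old, envir = globalenv()))
          set.seed(as.integer(seed))
          expr
        }
        withr_seed(sample.int(n_cells))
      })
    split(order_all[seq_len(n_remove_total)],
          rep(seq_len(n_events), times = per_event))
  }
  events <- unname(lapply(events, function(e) sort(as.integer(e))))
  structure(
    list(pattern = pattern,
         event_times = as.integer(start) + as.integer(interval) * (seq_len(n_events) - 1L),
         events = events, nx = nx, ny = ny,
         frac_per_event = frac_per_event, interval = as.integer(interval),
         start = as.integer(start), seed = seed,
         contracted_fitness = contracted_fitness),
    class = "contraction_schedule")
}

# Removal orderings. Each returns a permutation of all cell ids such that the
# first k are the first removed. Ties broken deterministically.

.cell_xy <- function(nx, ny) {
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  cbind(ix = ix, iy = iy, id = ix + (iy - 1L) * nx)
}

# remnant block for shrinkage: centered, 8 wide x 6 tall on 20x20 (48 cells);
# scales as ~2/5 of each dimension otherwise.
.shrink_block <- function(nx, ny) {
  bw <- max(2L, as.integer(round(nx * 8 / 20)))
  bh <- max(2L, as.integer(round(ny * 6 / 20)))
  x0 <- as.integer(floor((nx - bw) / 2)) + 1L
  y0 <- as.integer(floor((ny - bh) / 2)) + 1L
  c(x0 = x0, x1 = x0 + bw - 1L, y0 = y0, y1 = y0 + bh - 1L)
}

.order_shrinkage <- function(nx, ny) {
  cc <- .cell_xy(nx, ny)
  b <- .shrink_block(nx, ny)
  dx <- pmax(b["x0"] - cc[, "ix"], cc[, "ix"] - b["x1"], 0L)
  dy <- pmax(b["y0"] - cc[, "iy"], cc[, "iy"] - b["y1"], 0L)
  dcheb <- pmax(dx, dy)
  # peripheral rings first; within a ring, farthest from range center first
  dc <- (cc[, "ix"] - 0.5 - nx / 2)^2 + (cc[, "iy"] - 0.5 - ny / 2)^2
  cc[order(-dcheb, -dc, cc[, "id"]), "id"]
}

.order_amputation <- function(nx, ny) {
  cc <- .cell_xy(nx, ny)
  cc[order(cc[, "ix"], cc[, "iy"]), "id"]
}

# remnant corner patches for fragmentation (20x20): bottom-left 4x4,
# top-right 4x4, top-left 2x4, bottom-right 4x2 (48 cells).
.frag_patches <- function(nx, ny) {
  sx <- nx / 20; sy <- ny / 20
  r <- function(x0, x1, y0, y1) {
    ix <- max(1L, as.integer(ceiling(x0 * sx))):min(nx, as.integer(ceiling(x1 * sx)))
    iy <- max(1L, as.integer(ceiling(y0 * sy))):min(ny, as.integer(ceiling(y1 * sy)))
    as.integer(outer(ix, (iy - 1L) * nx, `+`))
  }
  list(bottomleft = r(1, 4, 1, 4),
       topright   = r(nx - 3, nx, ny - 3, ny),
       topleft    = r(1, 2, ny - 3, ny),
       bottomright = r(nx - 3, nx, 1, 2))
}

.order_fragmentation <- function(nx, ny) {
  cc <- .cell_xy(nx, ny)
  keep <- unlist(.frag_patches(nx, ny))
  removable <- setdiff(cc[, "id"], keep)
  # central cross first: nearest the range center removed earliest
  dc <- (cc[, "ix"] - 0.5 - nx / 2)^2 + (cc[, "iy"] - 0.5 - ny / 2)^2
  ord <- cc[order(dc, cc[, "id"]), "id"]
  c(ord[ord %in% removable], ord[ord %in% keep])
}

#' @export
print.contraction_schedule <- function(x, ...) {
  cat(sprintf("<contraction_schedule> pattern '%s' on a %d x %d grid\n",
              x$pattern, x$nx, x$ny))
  if (length(x$events) == 0L) {
    cat("  no events (control)\n")
  } else {
    cat(sprintf("  %d events at timesteps %s; %s cells per event (%.0f%% total)\n",
                length(x$events),
                paste(x$event_times, collapse = ", "),
                paste(lengths(x$events), collapse = ", "),
                100 * sum(lengths(x$events)) / (x$nx * x$ny)))
  }
  invisible(x)
}

#' Apply one contraction event to a grid
#'
#' Sets the habitat fitness of the listed cells to \code{value} and leaves all
#' other cells unchanged.
#'
#' @param grid A \code{\link{fitness_grid}}.
#' @param cells Integer vector of cell ids (column-major linear indices).
#' @param value New fitness for those cells (default 0.1).
#' @return The modified \code{fitness_grid}.
#' @export
apply_contraction <- function(grid, cells, value = 0.1) {
  stopifnot(inherits(grid, "fitness_grid"))
  cells <- as.integer(cells)
  if (length(cells) == 0L) return(grid)
  if (any(is.na(cells)) || any(cells < 1L | cells > grid$nx * grid$ny))
    stop("cell index outside grid")
  grid$values[cells] <- value
  grid
}

#' Grid after the first k events of a schedule
#'
#' @param schedule A \code{\link{contraction_schedule}}.
#' @param k Number of events applied (default: all).
#' @param init_fitness Pre-contraction fitness.
#' @return A \code{\link{fitness_grid}}.
#' @export
schedule_grid <- function(schedule, k = length(schedule$events),
                          init_fitness = 1.0) {
  stopifnot(inherits(schedule, "contraction_schedule"))
  g <- fitness_grid(schedule$nx, schedule$ny, init_fitness)
  for (ev in schedule$events[seq_len(k)])
    g <- apply_contraction(g, ev, schedule$contracted_fitness)
  g
}

#' Connected components of habitable cells
#'
#' Labels 4-neighbour connected components among cells whose fitness exceeds
#' \code{threshold}. Used to check that fragmentation schedules actually sever
#' the range into disjoint patches.
#'
#' @param grid A \code{\link{fitness_grid}}.
#' @param threshold Cells with values strictly above this are habitable.
#' @return Integer matrix (same shape as the grid values): component label per
#'   habitable cell, 0 for contracted cells.
#' @export
habitable_components <- function(grid, threshold = 0.5) {
  stopifnot(inherits(grid, "fitness_grid"))
  good <- grid$values > threshold
  lab <- matrix(0L, grid$nx, grid$ny)
  cur <- 0L
  for (start in which(good)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      id <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (lab[id] != 0L) next
      lab[id] <- cur
      ix <- ((id - 1L) %% grid$nx) + 1L
      iy <- ((id - 1L) %/% grid$nx) + 1L
      for (nb in c(if (ix > 1L) id - 1L, if (ix < grid$nx) id + 1L,
                   if (iy > 1L) id - grid$nx, if (iy < grid$ny) id + grid$nx))
        if (good[nb] && lab[nb] == 0L) stack <- c(stack, nb)
    }
  }
  lab
}

#' Serialize a schedule to YAML / read it back
#'
#' @param schedule A \code{\link{contraction_schedule}}.
#' @param path File path.
#' @return \code{write_schedule_yaml} returns \code{path} invisibly;
#'   \code{read_schedule_yaml} returns the \code{contraction_schedule}.
#' @export
write_schedule_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "contraction_schedule"))
  x <- unclass(schedule)
  x$events <- lapply(x$events, as.integer)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  contraction_schedule(x$pattern, x$nx, x$ny,
                       n_events = length(x$events),
                       frac_per_event = x$frac_per_event,
                       interval = x$interval, start = x$start, seed = x$seed,
                       contracted_fitness = x$contracted_fitness,
                       custom_events = if (x$pattern == "none") NULL else x$events)
}

#' Export grid snapshots as TSV matrices
#'
#' Writes one plain-text matrix (rows = y from top, columns = x) per event
#' state: pre-contraction plus after each event.
#'
#' @param schedule A \code{\link{contraction_schedule}}.
#' @param dir Output directory.
#' @return Character vector of written file paths, invisibly.
#' @export
write_grid_snapshots <- function(schedule, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in 0:length(schedule$events)) {
    g <- schedule_grid(schedule, k)
    p <- file.path(dir, sprintf("grid_%s_event%d.tsv", schedule$pattern, k))
    # top row of the file = top of the range
    utils::write.table(t(g$values)[g$ny:1, , drop = FALSE], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
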