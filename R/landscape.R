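# Synthetic replication-kinetics landscapes and read sampling.
#
# A landscape is a deterministic replication-kinetics model for one
# chromosome: origins fire at fixed times (fractions of S phase) and forks
# proceed outward at constant speed, so the replication time of every
# position is the minimum arrival time over origins. S-phase cells are
# sampled uniformly through S-phase progression, which makes the expected
# copy number affine in timing: c(x) = 2 - tau(x). These curves drive
# multinomial read sampling for G1 (uniform, up to bias) and S libraries
# and give every downstream stage an analytic ground truth.

#' Construct a replication-kinetics landscape
#'
#' @param chrom Chromosome name (single string).
#' @param chrom_length Chromosome length in bp.
#' @param origins `data.frame` with columns `position` (bp, strictly
#'   increasing, within `[0, chrom_length)`) and `firing_time` (fraction of
#'   S phase, in `[0, 1)`).
#' @param fork_speed Fork speed in bp per unit S-phase fraction (> 0).
#' @param gaps Optional `data.frame` with columns `start`, `end` (bp,
#'   0-based half-open) of unmappable intervals (e.g. rDNA placeholders):
#'   sorted, non-overlapping; no reads are ever emitted inside them.
#'
#' @return An object of class `"landscape"`.
#' @export
landscape <- function(chrom, chrom_length, origins, fork_speed, gaps = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  chrom_length <- as.numeric(chrom_length)
  stopifnot(is.finite(chrom_length), chrom_length > 0)
  if (!is.data.frame(origins) ||
      !all(c("position", "firing_time") %in% names(origins)))
    stop("origins must be a data.frame with columns position and firing_time")
  if (nrow(origins) == 0L) stop("no origins")
  pos <- as.numeric(origins$position)
  ft <- as.numeric(origins$firing_time)
  if (any(diff(pos) <= 0)) stop("origin positions must be strictly increasing")
  if (any(pos < 0 | pos >= chrom_length))
    stop("origin positions must lie within [0, chrom_length)")
  if (any(ft < 0 | ft >= 1)) stop("firing_time must lie in [0, 1)")
  if (!is.finite(fork_speed) || fork_speed <= 0) stop("fork_speed must be > 0")
  if (!is.null(gaps)) {
    stopifnot(is.data.frame(gaps), all(c("start", "end") %in% names(gaps)))
    gaps <- data.frame(start = as.numeric(gaps$start),
                       end = as.numeric(gaps$end))
    if (nrow(gaps)) {
      if (any(gaps$start >= gaps$end)) stop("gap start must be < end")
      if (any(gaps$start < 0 | gaps$end > chrom_length))
        stop("gaps must lie within the chromosome")
      if (is.unsorted(gaps$start) || any(gaps$start[-1L] < gaps$end[-nrow(gaps)]))
        stop("gaps must be sorted and non-overlapping")
    } else {
      gaps <- NULL
    }
  }
  structure(
    list(chrom = chrom, chrom_length = chrom_length,
         origins = data.frame(position = pos, firing_time = ft),
         fork_speed = as.numeric(fork_speed), gaps = gaps),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %s: %.3g bp, %d origins, fork speed %.3g bp/S-unit, %d gaps\n",
              x$chrom, x$chrom_length, nrow(x$origins), x$fork_speed,
              if (is.null(x$gaps)) 0L else nrow(x$gaps)))
  invisible(x)
}

#' Replication timing curve of a landscape
#'
#' tau(x) = min over origins i of t_i + |x - x_i| / v, capped at 1 (the end
#' of S phase). Continuous and piecewise linear; tau(x_i) = t_i at each
#' origin, and local maxima occur only between origins.
#'
#' @param landscape A [landscape()].
#' @param positions Numeric vector of bp positions in `[0, chrom_length)`.
#' @return Replication times in `[0, 1]`, one per position.
#' @export
timing_curve <- function(landscape, positions) {
  stopifnot(inherits(landscape, "landscape"))
  positions <- as.numeric(positions)
  if (any(positions < 0 | positions >= landscape$chrom_length))
    stop("positions must lie within [0, chrom_length)")
  ors <- landscape$origins
  if (nrow(ors) == 0L) stop("no origins")
  tau <- rep(Inf, length(positions))
  for (i in seq_len(nrow(ors))) {
    tau <- pmin(tau, ors$firing_time[i] +
                  abs(positions - ors$position[i]) / landscape$fork_speed)
  }
  pmin(tau, 1)
}

#' Expected copy number from replication timing
#'
#' With S-phase cells sampled uniformly through S-phase progression, a locus
#' replicating at time tau has been duplicated in a fraction (1 - tau) of
#' the S population, so its expected copy number is c = 1 + (1 - tau) =
#' 2 - tau: 2 for tau = 0 (replicated in all S cells), 1 for tau = 1.
#'
#' @param tau Numeric vector of replication times in `[0, 1]`.
#' @return Expected copies in `[1, 2]`, strictly decreasing in tau.
#' @export
copy_number_curve <- function(tau) {
  tau <- as.numeric(tau)
  if (any(!is.finite(tau)) || any(tau < 0 | tau > 1))
    stop("tau must lie in [0, 1]")
  2 - tau
}

#' Simulation configuration
#'
#' @param n_reads_g1,n_reads_s Read counts per library (> 0).
#' @param bias Optional vectorized function of bp position returning a
#'   non-negative relative mappability/GC weight; `NULL` means constant 1.
#' @param seed Optional integer seed; when set, [sample_reads()] is
#'   reproducible (the S phase uses `seed + 1` so the two libraries are
#'   independent draws).
#' @param tile Sampling tile width in bp: weights are evaluated at tile
#'   midpoints and positions drawn uniformly within tiles. 1 kb by default,
#'   small against both bin widths and fork travel per tile.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_reads_g1, n_reads_s, bias = NULL, seed = NULL,
                       tile = 1000L) {
  stopifnot(n_reads_g1 > 0, n_reads_s > 0, tile >= 1)
  if (!is.null(bias) && !is.function(bias))
    stop("bias must be NULL or a vectorized function of position")
  structure(list(n_reads_g1 = as.numeric(n_reads_g1),
                 n_reads_s = as.numeric(n_reads_s),
                 bias = bias, seed = seed, tile = as.numeric(tile)),
            class = "sim_config")
}

# Per-tile sampling weights for one landscape and phase.
.tile_weights <- function(landscape, phase, bias = NULL, tile = 1000) {
  L <- landscape$chrom_length
  n_tiles <- ceiling(L / tile)
  t_start <- (seq_len(n_tiles) - 1) * tile
  t_end <- pmin(t_start + tile, L)
  mid <- (t_start + t_end) / 2
  w <- if (is.null(bias)) rep(1, n_tiles) else as.numeric(bias(mid))
  if (any(w < 0)) stop("bias weights must be >= 0")
  if (phase == "S") w <- w * copy_number_curve(timing_curve(landscape, mid))
  # fraction of each tile outside gaps
  if (!is.null(landscape$gaps)) {
    cov <- numeric(n_tiles)
    for (g in seq_len(nrow(landscape$gaps))) {
      cov <- cov + pmax(0, pmin(t_end, landscape$gaps$end[g]) -
                          pmax(t_start, landscape$gaps$start[g]))
    }
    w <- w * (1 - cov / (t_end - t_start))
  }
  w <- w * (t_end - t_start) / tile    # shorter terminal tile
  list(start = t_start, end = t_end, weight = w)
}

# Membership of positions in a sorted non-overlapping interval set.
.in_intervals <- function(pos, start, end) {
  if (length(start) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, start)
  idx > 0L & pos < end[pmax(idx, 1L)]
}

# Draw n read start positions for one landscape/phase from ambient RNG.
.sample_reads_n <- function(landscape, n, phase, bias = NULL, tile = 1000) {
  tw <- .tile_weights(landscape, phase, bias, tile)
  if (all(tw$weight <= 0)) stop("all sampling weights are zero")
  counts <- as.vector(stats::rmultinom(1L, n, tw$weight))
  idx <- rep.int(seq_along(counts), counts)
  width <- (tw$end - tw$start)[idx]
  pos <- tw$start[idx] + floor(stats::runif(length(idx)) * width)
  if (!is.null(landscape$gaps)) {
    repeat {
      bad <- .in_intervals(pos, landscape$gaps$start, landscape$gaps$end)
      if (!any(bad)) break
      pos[bad] <- tw$start[idx][bad] +
        floor(stats::runif(sum(bad)) * width[bad])
    }
  }
  data.frame(chrom = rep(landscape$chrom, length(pos)),
             pos = sort(pos), stringsAsFactors = FALSE)
}

#' Sample a read set from a landscape
#'
#' Draws exactly `n_reads` read start positions multinomially with per-bp
#' weight `bias` (G1) or `bias * c(x)` (S), zero inside gaps; output is
#' sorted and reproducible under a fixed config seed.
#'
#' @param landscape A [landscape()].
#' @param config A [sim_config()].
#' @param phase `"G1"` or `"S"`.
#' @return `data.frame` with columns `chrom`, `pos` (sorted read starts).
#' @export
sample_reads <- function(landscape, config, phase = c("G1", "S")) {
  phase <- match.arg(phase)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + (phase == "S"))
  n <- if (phase == "G1") config$n_reads_g1 else config$n_reads_s
  .sample_reads_n(landscape, n, phase, config$bias, config$tile)
}

#' Generate a genome of random landscapes
#'
#' Origin positions are uniform (with a minimum separation), firing times
#' uniform over `firing_range`. Defaults describe a realistic human-like
#' world: fork speed 1e6 bp per unit S phase (about 2 kb/min over an 8 h
#' S phase) and firing times spread over the first half of S phase.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp); recycled.
#' @param origins_per_chrom Origins per chromosome; recycled.
#' @param fork_speed bp per unit S-phase fraction.
#' @param firing_range Range of uniform firing times.
#' @param min_origin_gap Minimum spacing between origins (bp).
#' @param gaps Optional named list (by chromosome) of gap `data.frame`s.
#' @param chrom_names Chromosome names; default `chr1..chrN`.
#' @return Named list of [landscape()] objects. Uses the ambient RNG stream;
#'   call `set.seed()` first for reproducibility.
#' @export
sim_genome_landscapes <- function(n_chrom = 22, chrom_length = 4e6,
                                  origins_per_chrom = 3, fork_speed = 1e6,
                                  firing_range = c(0, 0.5),
                                  min_origin_gap = 5e4, gaps = NULL,
                                  chrom_names = NULL) {
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chrom))
  stopifnot(length(chrom_names) == n_chrom)
  chrom_length <- rep_len(as.numeric(chrom_length), n_chrom)
  origins_per_chrom <- rep_len(as.integer(origins_per_chrom), n_chrom)
  out <- vector("list", n_chrom)
  names(out) <- chrom_names
  for (i in seq_len(n_chrom)) {
    pos <- .draw_origin_positions(origins_per_chrom[i], chrom_length[i],
                                  min_origin_gap)
    ft <- stats::runif(origins_per_chrom[i], firing_range[1], firing_range[2])
    out[[i]] <- landscape(
      chrom = chrom_names[i], chrom_length = chrom_length[i],
      origins = data.frame(position = pos, firing_time = ft),
      fork_speed = fork_speed,
      gaps = if (!is.null(gaps)) gaps[[chrom_names[i]]] else NULL
    )
  }
  out
}

# Uniform positions conditional on a minimum pairwise gap: shrink the
# chromosome by (k-1) gaps, draw sorted uniforms, re-expand. Exact.
.draw_origin_positions <- function(k, L, min_gap) {
  slack <- L - (k - 1) * min_gap
  if (slack <= 0)
    stop("chromosome too short for the requested origin spacing")
  u <- sort(stats::runif(k, 0, slack))
  floor(u + (seq_len(k) - 1) * min_gap)
}

#' Sample a genome-wide read set
#'
#' Splits `n_reads` across chromosomes multinomially by total sampling
#' weight, then samples within each chromosome. Ambient RNG.
#'
#' @param landscapes Named list of [landscape()]s.
#' @inheritParams sample_reads
#' @param n_reads Total reads across the genome.
#' @param bias,tile See [sim_config()].
#' @return `data.frame` with columns `chrom`, `pos`.
#' @export
sample_reads_genome <- function(landscapes, n_reads, phase = c("G1", "S"),
                                bias = NULL, tile = 1000) {
  phase <- match.arg(phase)
  wsum <- vapply(landscapes, function(ls)
    sum(.tile_weights(ls, phase, bias, tile)$weight), numeric(1))
  if (all(wsum <= 0)) stop("all sampling weights are zero")
  split <- as.vector(stats::rmultinom(1L, n_reads, wsum))
  parts <- vector("list", length(landscapes))
  for (i in seq_along(landscapes)) {
    parts[[i]] <- if (split[i] > 0)
      .sample_reads_n(landscapes[[i]], split[i], phase, bias, tile)
    else
      data.frame(chrom = character(0), pos = numeric(0))
  }
  do.call(rbind, parts)
}

#' Simulate a paired G1/S experiment
#'
#' @param landscapes Named list of [landscape()]s.
#' @param n_reads_g1,n_reads_s Total reads per library.
#' @param seed Optional integer seed set once before sampling.
#' @param bias,tile See [sim_config()].
#' @return List with elements `g1` and `s` (read `data.frame`s) and
#'   `genome` (a descriptor from [genome_of()]).
#' @export
simulate_experiment <- function(landscapes, n_reads_g1, n_reads_s,
                                seed = NULL, bias = NULL, tile = 1000) {
  if (!is.null(seed)) set.seed(seed)
  list(g1 = sample_reads_genome(landscapes, n_reads_g1, "G1", bias, tile),
       s = sample_reads_genome(landscapes, n_reads_s, "S", bias, tile),
       genome = genome_of(landscapes))
}

#' Genome descriptor of a set of landscapes
#'
#' @param landscapes Named list of [landscape()]s.
#' @return `data.frame` with columns `chrom`, `length`, `autosome`.
#' @export
genome_of <- function(landscapes) {
  genome_descriptor(vapply(landscapes, `[[`, character(1), "chrom"),
                    vapply(landscapes, `[[`, numeric(1), "chrom_length"))
}

#' Shift origin firing times inside a region
#'
#' Utility for constructing samples that differ only in the timing of a
#' region (e.g. earlier- or later-replicating centromeres): firing times of
#' origins with position in `[start, end)` are shifted by `delta` and
#' clamped to `[0, 1)`.
#'
#' @param landscape A [landscape()].
#' @param start,end Region bounds (bp, half-open).
#' @param delta Firing-time shift (fraction of S phase; negative = earlier).
#' @return A new [landscape()].
#' @export
shift_firing_times <- function(landscape, start, end, delta) {
  stopifnot(inherits(landscape, "landscape"))
  ors <- landscape$origins
  sel <- ors$position >= start & ors$position < end
  ors$firing_time[sel] <- pmin(pmax(ors$firing_time[sel] + delta, 0), 1 - 1e-9)
  landscape(landscape$chrom, landscape$chrom_length, ors,
            landscape$fork_speed, landscape$gaps)
}

#' Write the analytic truth curves of a landscape
#'
#' Writes tau(x) and c(x), evaluated at fixed-resolution tile midpoints, as
#' bedGraph files, and the landscape itself as a JSON sidecar.
#'
#' @param landscape A [landscape()].
#' @param dir Output directory (created if needed).
#' @param res Resolution in bp (default 1 kb).
#' @return Invisibly, the paths written.
#' @export
write_landscape_truth <- function(landscape, dir, res = 1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- landscape$chrom_length
  start <- seq(0, L - 1, by = res)
  end <- pmin(start + res, L)
  tau <- timing_curve(landscape, (start + end) / 2)
  paths <- c(tau = file.path(dir, paste0(landscape$chrom, ".tau.bedGraph")),
             cn = file.path(dir, paste0(landscape$chrom, ".copies.bedGraph")),
             json = file.path(dir, paste0(landscape$chrom, ".landscape.json")))
  write_bedgraph(data.frame(chrom = landscape$chrom, start = start, end = end,
                            value = tau), paths[["tau"]])
  write_bedgraph(data.frame(chrom = landscape$chrom, start = start, end = end,
                            value = copy_number_curve(tau)), paths[["cn"]])
  jsonlite::write_json(
    list(chrom = landscape$chrom, chrom_length = landscape$chrom_length,
         origins = landscape$origins, fork_speed = landscape$fork_speed,
         gaps = landscape$gaps),
    paths[["json"]], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
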