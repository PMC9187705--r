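# Shared synthetic worlds. All builders draw from the ambient RNG stream:
# callers set.seed() first. The "benchmark" world is the package's stated
# parameter-recovery world: near-regular strong initiation zones (2 Mb mean
# spacing, >= 1.9 Mb apart), early-concentrated firing (U[0, 0.2]) and a
# timing-front speed of 1e6 bp per unit S phase, chosen so every origin
# fires actively and nearly all loci finish replicating within S phase.

benchmark_landscape <- function(chrom = "chr1", L = 1e8, n_origins = 50) {
  sim_genome_landscapes(
    n_chrom = 1, chrom_length = L, origins_per_chrom = n_origins,
    fork_speed = 1e6, firing_range = c(0, 0.2), min_origin_gap = 1.9e6,
    chrom_names = chrom)[[1]]
}

# Small multi-chromosome genome in the same world family; origin spacing
# scales with chromosome length to stay near-regular.
small_genome <- function(n_chrom = 22, L = 4e6, origins = 3) {
  sim_genome_landscapes(
    n_chrom = n_chrom, chrom_length = L, origins_per_chrom = origins,
    fork_speed = 1e6, firing_range = c(0, 0.2),
    min_origin_gap = 0.9 * L / origins)
}

# Centromere-ranking base world: 22 chromosomes of 5 Mb, five origins on a
# jittered 1-Mb grid (one always inside the central [2, 3) Mb "centromere"),
# firing in [0.2, 0.5] so +/- 0.1 shifts stay within S phase.
cen_base_landscapes <- function(n_chrom = 22) {
  out <- vector("list", n_chrom)
  names(out) <- paste0("chr", seq_len(n_chrom))
  for (i in seq_len(n_chrom)) {
    pos <- sort(round(seq(5e5, 4.5e6, by = 1e6) +
                        stats::runif(5, -2e5, 2e5)))
    out[[i]] <- landscape(names(out)[i], 5e6,
                          data.frame(position = pos,
                                     firing_time = stats::runif(5, 0.2, 0.5)),
                          fork_speed = 1e6)
  }
  out
}

cen_regions <- function(landscapes) {
  data.frame(chrom = names(landscapes), start = 2e6, end = 3e6,
             stringsAsFactors = FALSE)
}

# Minimal profile-shaped data.frame for unit tests that exercise dynamics
# and region logic without a simulation.
fake_profile <- function(rt, centers = seq_along(rt) * 1e5, chrom = "chr1",
                         segment_id = 1L, width = 1e4) {
  structure(
    data.frame(chrom = chrom, start = centers - width / 2,
               end = centers + width / 2, center = centers,
               raw_ratio = rt, smoothed = rt, rt = rt,
               segment_id = segment_id, stringsAsFactors = FALSE),
    class = c("rt_profile", "data.frame"))
}
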