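# Variable-size bins of uniform G1 coverage.
#
# The G1 library is a uniform two-copy baseline, so bins holding a fixed
# number of G1 read starts (200 by default) automatically absorb
# mappability, GC and copy-number variation: a region with doubled G1
# density gets half-width bins and the S/G1 ratio stays unbiased. No
# separate CNV-calling stage exists; this is the mechanism.

#' Define variable-size bins of uniform G1 coverage
#'
#' Walks each chromosome's sorted G1 read starts and cuts consecutive bins
#' of exactly `reads_per_bin` reads. The boundary between two bins is the
#' midpoint between the last read of one and the first read of the next
#' (rounded up so the earlier read stays inside its bin; coincident reads
#' put the boundary just after them). The first bin starts at the first
#' read; a trailing remainder of fewer than `reads_per_bin` reads is
#' dropped and counted in the run report. Chromosomes with fewer than
#' `reads_per_bin` reads are skipped with a warning.
#'
#' @param g1_reads `data.frame` with columns `chrom`, `pos` (sorted within
#'   chromosomes).
#' @param reads_per_bin G1 reads per bin (>= 2; default 200).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `g1_count`
#'   and attribute `"report"` (per-chromosome bins and dropped reads).
#' @export
define_bins <- function(g1_reads, reads_per_bin = 200L) {
  stopifnot(all(c("chrom", "pos") %in% names(g1_reads)), reads_per_bin >= 2)
  reads_per_bin <- as.integer(reads_per_bin)
  chroms <- unique(g1_reads$chrom)
  out <- vector("list", length(chroms))
  report <- list()
  for (k in seq_along(chroms)) {
    pos <- g1_reads$pos[g1_reads$chrom == chroms[k]]
    if (is.unsorted(pos)) stop("g1 reads must be sorted within chromosomes")
    n_full <- length(pos) %/% reads_per_bin
    dropped <- length(pos) - n_full * reads_per_bin
    if (n_full == 0L) {
      warning(sprintf("chromosome %s has fewer than %d G1 reads; skipped",
                      chroms[k], reads_per_bin))
      report[[chroms[k]]] <- list(n_bins = 0L, dropped_reads = dropped)
      next
    }
    j <- seq_len(n_full - 1L)
    last <- pos[j * reads_per_bin]        # last read of bin j
    nxt <- pos[j * reads_per_bin + 1L]    # first read of bin j+1
    boundary <- ifelse(nxt > last, ceiling((last + nxt) / 2), last + 1)
    starts <- c(pos[1L], boundary)
    ends <- c(boundary, pos[n_full * reads_per_bin] + 1)
    if (any(ends <= starts))
      stop(sprintf("degenerate bins on %s (heavily duplicated positions?)",
                   chroms[k]))
    out[[k]] <- data.frame(chrom = chroms[k], start = starts, end = ends,
                           g1_count = reads_per_bin,
                           stringsAsFactors = FALSE)
    report[[chroms[k]]] <- list(n_bins = n_full, dropped_reads = dropped)
  }
  bins <- do.call(rbind, out)
  if (is.null(bins))
    bins <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), g1_count = integer(0))
  attr(bins, "report") <- report
  attr(bins, "reads_per_bin") <- reads_per_bin
  bins
}

#' Count S-phase reads per bin
#'
#' A read with start in `[bin.start, bin.end)` belongs to that bin
#' (half-open: a read exactly at `bin.end` counts in the next bin). Reads
#' outside the binned span are ignored.
#'
#' @param bins Bin table from [define_bins()].
#' @param s_reads `data.frame` with columns `chrom`, `pos` (sorted within
#'   chromosomes).
#' @return `bins` with an `s_count` column added.
#' @export
count_s_reads <- function(bins, s_reads) {
  stopifnot(all(c("chrom", "pos") %in% names(s_reads)))
  bins$s_count <- 0L
  for (ch in unique(bins$chrom)) {
    sel <- bins$chrom == ch
    pos <- s_reads$pos[s_reads$chrom == ch]
    if (length(pos) == 0L) next
    if (is.unsorted(pos)) stop("s reads must be sorted within chromosomes")
    breaks <- c(bins$start[sel], bins$end[sel][sum(sel)])
    idx <- findInterval(pos, breaks)
    idx <- idx[idx >= 1L & idx <= sum(sel) & pos < breaks[length(breaks)]]
    bins$s_count[sel] <- tabulate(idx, nbins = sum(sel))
  }
  bins
}

#' Library-size-normalized S/G1 ratio per bin
#'
#' `ratio_j = (s_j / sum(S)) / (g1_j / sum(G1))`, sums over retained bins
#' genome-wide, so the g1-weighted mean ratio is 1. After this
#' normalization, fluctuations reflect only replication timing (early
#' regions over-represented in S).
#'
#' @param bins Bin table with `g1_count` and `s_count`.
#' @return `bins` with a `ratio` column added.
#' @export
s_over_g1 <- function(bins) {
  stopifnot(all(c("g1_count", "s_count") %in% names(bins)))
  tot_s <- sum(bins$s_count)
  tot_g1 <- sum(bins$g1_count)
  if (tot_s == 0) stop("no S reads within the binned span")
  bins$ratio <- (bins$s_count / tot_s) / (bins$g1_count / tot_g1)
  bins
}

#' G1/S binning pipeline
#'
#' [define_bins()] + [count_s_reads()] + [s_over_g1()] in one call.
#'
#' @inheritParams define_bins
#' @inheritParams count_s_reads
#' @return Bin table with `g1_count`, `s_count`, `ratio`.
#' @export
bin_reads <- function(g1_reads, s_reads, reads_per_bin = 200L) {
  s_over_g1(count_s_reads(define_bins(g1_reads, reads_per_bin), s_reads))
}
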