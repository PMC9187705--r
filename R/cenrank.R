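# Cross-sample centromere comparison: relative-position average profiles
# and per-chromosome earliest-to-latest rankings.

#' Average profile over regions in relative coordinates
#'
#' Each region's interior is divided into `n_bins` equally spaced relative
#' bins (bin k spans `[start + k*L/n_bins, start + (k+1)*L/n_bins)`); the
#' flanking `flank` bp on either side use fixed `flank_bin_width` absolute
#' bins. A profile bin contributes to the relative bin containing its
#' center; region means are averaged across regions by relative bin index.
#' Relative bins with no data are NA (missing, never zero).
#'
#' @param profile An `"rt_profile"`.
#' @param regions Non-overlapping interval `data.frame` (`chrom`, `start`,
#'   `end`).
#' @param n_bins Interior bins per region (default 100).
#' @param flank Flank size in bp on each side (default 5 Mb).
#' @param flank_bin_width Absolute width of flank bins (default 50 kb;
#'   `flank` must be a multiple).
#' @param genome Optional genome descriptor; regions extending beyond
#'   chromosome bounds are an error.
#' @return `data.frame` with columns `rel_index` (negative = left flank,
#'   `1..n_bins` interior, `> n_bins` right flank), `section`, `mean_rt`,
#'   `n_regions`.
#' @export
relative_profile <- function(profile, regions, n_bins = 100L, flank = 5e6,
                             flank_bin_width = 5e4, genome = NULL) {
  stopifnot(n_bins >= 1, flank >= 0, flank_bin_width > 0)
  n_flank <- flank / flank_bin_width
  if (n_flank != round(n_flank))
    stop("flank must be a multiple of flank_bin_width")
  n_flank <- as.integer(n_flank)
  if (!is.null(genome)) {
    len <- genome$length[match(regions$chrom, genome$chrom)]
    if (any(is.na(len)) || any(regions$start < 0 | regions$end > len))
      stop("region outside chromosome bounds")
  }
  idx_all <- c(seq(-n_flank, -1L, length.out = n_flank),
               seq_len(n_bins),
               if (n_flank) n_bins + seq_len(n_flank))
  acc_sum <- stats::setNames(numeric(length(idx_all)), idx_all)
  acc_n <- acc_sum
  for (r in seq_len(nrow(regions))) {
    rs <- regions$start[r]; re <- regions$end[r]
    L <- re - rs
    sub <- profile[profile$chrom == regions$chrom[r], , drop = FALSE]
    ctr <- sub$center
    rel <- rep(NA_real_, nrow(sub))
    int_sel <- ctr >= rs & ctr < re
    rel[int_sel] <- floor((ctr[int_sel] - rs) / (L / n_bins)) + 1
    if (n_flank) {
      lf <- ctr >= rs - flank & ctr < rs
      rel[lf] <- -ceiling((rs - ctr[lf]) / flank_bin_width)
      rf <- ctr >= re & ctr < re + flank
      rel[rf] <- n_bins + floor((ctr[rf] - re) / flank_bin_width) + 1
    }
    ok <- !is.na(rel)
    if (!any(ok)) next
    region_mean <- tapply(sub$rt[ok], rel[ok], mean)
    key <- names(region_mean)
    acc_sum[key] <- acc_sum[key] + as.numeric(region_mean)
    acc_n[key] <- acc_n[key] + 1
  }
  out <- data.frame(
    rel_index = as.integer(idx_all),
    section = ifelse(idx_all < 1, "left_flank",
                     ifelse(idx_all <= n_bins, "interior", "right_flank")),
    mean_rt = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_),
    n_regions = as.integer(acc_n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank samples by centromeric replication timing, per chromosome
#'
#' For each chromosome carrying a region, samples are ordered by descending
#' median rt over bins whose centers fall inside that chromosome's region
#' intervals (rank 1 = earliest). Ties are broken lexicographically by
#' sample name and flagged. Chromosomes where any sample has no region bins
#' are excluded (logged via `message()`).
#'
#' @param profiles Named list (>= 2) of `"rt_profile"` objects.
#' @param regions Interval `data.frame` (`chrom`, `start`, `end`).
#' @return List with `rankings` (`data.frame`: `chrom`, `sample`, `rank`,
#'   `median_rt`, `tied`), `rank_counts` (samples x ranks matrix; rows sum
#'   to the number of scored chromosomes), and `excluded` chromosomes.
#' @export
rank_samples <- function(profiles, regions) {
  stopifnot(is.list(profiles), length(profiles) >= 2,
            !is.null(names(profiles)))
  samples <- names(profiles)
  chroms <- unique(regions$chrom)
  rows <- list()
  excluded <- character(0)
  for (ch in chroms) {
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    reg <- reg[order(reg$start), , drop = FALSE]
    med <- vapply(profiles, function(p) {
      sub <- p[p$chrom == ch, , drop = FALSE]
      vals <- sub$rt[.in_intervals(sub$center, reg$start, reg$end)]
      if (length(vals) == 0L) NA_real_ else stats::median(vals)
    }, numeric(1))
    if (any(is.na(med))) {
      excluded <- c(excluded, ch)
      message(sprintf("rank_samples: chromosome %s excluded (sample without centromeric bins)",
                      ch))
      next
    }
    ord <- order(-med, samples)
    tied <- duplicated(med[ord]) | duplicated(med[ord], fromLast = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, sample = samples[ord], rank = seq_along(samples),
      median_rt = med[ord], tied = tied, stringsAsFactors = FALSE)
  }
  rankings <- if (length(rows)) do.call(rbind, rows)
              else data.frame(chrom = character(0), sample = character(0),
                              rank = integer(0), median_rt = numeric(0),
                              tied = logical(0))
  rownames(rankings) <- NULL
  counts <- matrix(0L, nrow = length(samples), ncol = length(samples),
                   dimnames = list(samples, paste0("rank", seq_along(samples))))
  for (i in seq_len(nrow(rankings)))
    counts[rankings$sample[i], rankings$rank[i]] <-
      counts[rankings$sample[i], rankings$rank[i]] + 1L
  list(rankings = rankings, rank_counts = counts, excluded = excluded)
}
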