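# Replication timing profiles: segmentation at coverage gaps, per-segment
# spline smoothing, and autosome-anchored z-normalization.

#' Split a bin table into gap-free segments
#'
#' Consecutive bins whose center-to-center distance is at most `max_gap`
#' share a segment; larger gaps (e.g. across rDNA placeholder regions, where
#' no reads map and bins become very wide) start a new segment, so smoothing
#' never bridges them. Segments never cross chromosomes.
#'
#' @param bins Bin table sorted by chromosome then start.
#' @param max_gap Maximum center-to-center distance in bp (default 100 kb).
#' @return Integer vector of segment ids (unique genome-wide).
#' @export
segment_profile <- function(bins, max_gap = 1e5) {
  stopifnot(max_gap > 0)
  n <- nrow(bins)
  if (n == 0L) return(integer(0))
  centers <- (bins$start + bins$end) / 2
  new_seg <- c(TRUE, bins$chrom[-1L] != bins$chrom[-n] |
                 diff(centers) > max_gap)
  cumsum(new_seg)
}

#' Normalize smoothed values to autosomal mean 0, SD 1
#'
#' `rt = (smoothed - mu_auto) / sigma_auto`, with `mu_auto`/`sigma_auto`
#' the unweighted mean and SD over autosomal bins. chrX is scaled with the
#' autosomal statistics, not forced to mean 0.
#'
#' @param values Smoothed values, one per bin.
#' @param chrom Chromosome name per bin.
#' @return Numeric vector of rt z-scores with attributes `mu` and `sigma`.
#' @export
normalize_rt <- function(values, chrom) {
  auto <- is_autosome(chrom)
  if (sum(auto) < 2L) stop("need at least 2 autosomal bins to normalize")
  mu <- mean(values[auto])
  sigma <- stats::sd(values[auto])
  if (!is.finite(sigma) || sigma == 0) stop("degenerate profile")
  structure((values - mu) / sigma, mu = mu, sigma = sigma)
}

#' Build a replication timing profile from a bin table
#'
#' Segments the bins at coverage gaps, smooths the raw S/G1 ratio per
#' segment with a cubic smoothing spline ([smooth_segment()], csaps
#' convention, x in bp), and z-normalizes the smoothed values so autosomal
#' bins have mean 0 and SD 1 (positive rt = early replication). chrY bins
#' are dropped.
#'
#' @param bins Bin table with a `ratio` column (see [bin_reads()]).
#' @param p Spline smoothing parameter (default `1e-16`).
#' @param max_gap Segmentation gap in bp (default 100 kb).
#' @return `data.frame` of class `"rt_profile"` with columns `chrom`,
#'   `start`, `end`, `center`, `raw_ratio`, `smoothed`, `rt`, `segment_id`
#'   and attributes `p`, `max_gap`, `mu`, `sigma`.
#' @export
rt_profile <- function(bins, p = 1e-16, max_gap = 1e5) {
  stopifnot("ratio" %in% names(bins))
  if (any(drop <- .is_chry(bins$chrom))) {
    message(sprintf("rt_profile: dropping %d chrY bin(s)", sum(drop)))
    bins <- bins[!drop, , drop = FALSE]
  }
  ord <- order(match(bins$chrom, unique(bins$chrom)), bins$start)
  bins <- bins[ord, , drop = FALSE]
  seg <- segment_profile(bins, max_gap)
  centers <- (bins$start + bins$end) / 2
  smoothed <- numeric(nrow(bins))
  short <- 0L
  for (s in unique(seg)) {
    sel <- seg == s
    if (sum(sel) < 4L) {
      smoothed[sel] <- bins$ratio[sel]
      short <- short + 1L
    } else {
      smoothed[sel] <- smooth_segment(centers[sel], bins$ratio[sel], p)
    }
  }
  if (short > 0L)
    warning(sprintf("%d segment(s) shorter than 4 bins passed through unsmoothed",
                    short))
  rt <- normalize_rt(smoothed, bins$chrom)
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    center = centers, raw_ratio = bins$ratio,
                    smoothed = smoothed, rt = as.numeric(rt),
                    segment_id = seg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("rt_profile", "data.frame"),
            p = p, max_gap = max_gap,
            mu = attr(rt, "mu"), sigma = attr(rt, "sigma"))
}

#' Full S/G1 pipeline: reads to normalized profile
#'
#' @inheritParams bin_reads
#' @inheritParams rt_profile
#' @return An `"rt_profile"` (see [rt_profile()]).
#' @export
rt_pipeline <- function(g1_reads, s_reads, reads_per_bin = 200L,
                        p = 1e-16, max_gap = 1e5) {
  rt_profile(bin_reads(g1_reads, s_reads, reads_per_bin),
             p = p, max_gap = max_gap)
}

#' Evaluate a profile near arbitrary positions
#'
#' Nearest-bin lookup: each query gets the rt value of the closest bin
#' center on its chromosome, or NA if none lies within `max_gap`.
#'
#' @param profile An `"rt_profile"`.
#' @param chrom,pos Query positions (vectors of equal length).
#' @param max_gap Maximum center distance in bp (default 100 kb).
#' @return Numeric vector of rt values (NA where unevaluable).
#' @export
profile_at <- function(profile, chrom, pos, max_gap = 1e5) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    sub <- profile[profile$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ctr <- sub$center
    idx <- findInterval(pos[qi], ctr)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(ctr))
    d_lo <- abs(pos[qi] - ctr[lo])
    d_hi <- abs(pos[qi] - ctr[hi])
    best <- ifelse(d_lo <= d_hi, lo, hi)
    d <- pmin(d_lo, d_hi)
    ok <- d <= max_gap
    out[qi[ok]] <- sub$rt[best[ok]]
  }
  out
}

#' Write a profile as bedGraph
#'
#' @param profile An `"rt_profile"`.
#' @param path Output path.
#' @param what Which column to write: `"rt"` (default), `"smoothed"`, or
#'   `"raw_ratio"`.
#' @export
profile_to_bedgraph <- function(profile, path,
                                what = c("rt", "smoothed", "raw_ratio")) {
  what <- match.arg(what)
  write_bedgraph(profile, path, value_col = what)
}

#' Reconstruct a minimal profile from a bedGraph track
#'
#' Used by file-based workflows: rebuilds bin centers and segment ids from
#' interval geometry. `raw_ratio` and `smoothed` are not recoverable and are
#' set to the stored value.
#'
#' @param x `data.frame` from [read_bedgraph()].
#' @param max_gap Segmentation gap in bp.
#' @return An `"rt_profile"`-shaped `data.frame`.
#' @export
profile_from_bedgraph <- function(x, max_gap = 1e5) {
  ord <- order(match(x$chrom, unique(x$chrom)), x$start)
  x <- x[ord, , drop = FALSE]
  seg <- segment_profile(x, max_gap)
  structure(
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               center = (x$start + x$end) / 2, raw_ratio = x$value,
               smoothed = x$value, rt = x$value, segment_id = seg,
               stringsAsFactors = FALSE),
    class = c("rt_profile", "data.frame"), max_gap = max_gap)
}
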