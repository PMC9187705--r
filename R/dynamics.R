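# Replication dynamics: RT peaks and valleys, inter-origin distances, and
# peak slopes. Peaks of the smoothed profile proxy replication initiation
# zones; the distance between consecutive peaks proxies inter-origin
# distance and the rise from flanking valleys proxies fork speed.

# Extrema of one segment's rt sequence: discrete neighbor comparison with
# plateaus collapsed to their midpoint bin. Returns indices into the
# segment and kinds, alternating by construction.
.seg_extrema <- function(rt) {
  r <- rle(rt)
  v <- r$values
  m <- length(v)
  if (m < 3L) return(list(index = integer(0), kind = character(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- 2:(m - 1L)
  is_pk <- v[k] > v[k - 1L] & v[k] > v[k + 1L]
  is_vl <- v[k] < v[k - 1L] & v[k] < v[k + 1L]
  sel <- which(is_pk | is_vl)
  idx <- as.integer(floor((starts[k][sel] + ends[k][sel]) / 2))
  list(index = idx, kind = ifelse(is_pk[sel], "peak", "valley"))
}

# Prominence of each extremum against its neighbor extrema (segment end
# values anchor the edges): for a peak, the smaller drop to either anchor.
.prominences <- function(vals, kind, seg_first, seg_last) {
  K <- length(vals)
  if (K == 0L) return(numeric(0))
  left <- c(seg_first, vals[-K])
  right <- c(vals[-1L], seg_last)
  ifelse(kind == "peak",
         pmin(vals - left, vals - right),
         pmin(left - vals, right - vals))
}

# Drop the shallower of any adjacent same-kind pair until alternation holds.
.enforce_alternation <- function(df) {
  repeat {
    if (nrow(df) < 2L) return(df)
    same <- which(df$kind[-1L] == df$kind[-nrow(df)])
    if (length(same) == 0L) return(df)
    i <- same[1L]
    keep_first <- if (df$kind[i] == "peak") df$rt[i] >= df$rt[i + 1L]
                  else df$rt[i] <= df$rt[i + 1L]
    df <- df[-(if (keep_first) i + 1L else i), , drop = FALSE]
  }
}

#' Call peaks and valleys of a replication timing profile
#'
#' Discrete local maxima/minima of rt over bin centers within each segment;
#' plateaus collapse to their midpoint bin. With `min_prominence > 0`,
#' extrema shallower than the threshold (prominence measured against
#' neighboring extrema, z-units) are removed iteratively, re-enforcing
#' peak/valley alternation by discarding the shallower of any adjacent
#' same-kind pair.
#'
#' @param profile An `"rt_profile"`.
#' @param min_prominence Minimum prominence in z-units (default 0: keep
#'   every discrete extremum, mirroring "varying amplitudes").
#' @return `data.frame` with columns `chrom`, `position`, `rt`, `kind`,
#'   `prominence`, `segment_id`; peaks and valleys alternate within each
#'   segment.
#' @export
call_extrema <- function(profile, min_prominence = 0) {
  stopifnot(min_prominence >= 0)
  parts <- list()
  for (s in unique(profile$segment_id)) {
    sub <- profile[profile$segment_id == s, , drop = FALSE]
    ex <- .seg_extrema(sub$rt)
    if (length(ex$index) == 0L) next
    df <- data.frame(chrom = sub$chrom[ex$index],
                     position = sub$center[ex$index],
                     rt = sub$rt[ex$index], kind = ex$kind,
                     segment_id = s, stringsAsFactors = FALSE)
    seg_first <- sub$rt[1L]
    seg_last <- sub$rt[nrow(sub)]
    repeat {
      pr <- .prominences(df$rt, df$kind, seg_first, seg_last)
      if (nrow(df) == 0L || all(pr >= min_prominence)) {
        df$prominence <- pr
        break
      }
      df <- df[-which.min(pr), , drop = FALSE]
      df <- .enforce_alternation(df)
    }
    parts[[length(parts) + 1L]] <- df
  }
  out <- if (length(parts)) do.call(rbind, parts)
         else data.frame(chrom = character(0), position = numeric(0),
                         rt = numeric(0), kind = character(0),
                         segment_id = integer(0), prominence = numeric(0))
  rownames(out) <- NULL
  out[c("chrom", "position", "rt", "kind", "prominence", "segment_id")]
}

# Half-open membership of positions in a (chrom, start, end) interval set.
.points_in_regions <- function(chrom, pos, regions) {
  inside <- rep(FALSE, length(pos))
  for (ch in unique(regions$chrom)) {
    sub <- regions[regions$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    qi <- which(chrom == ch)
    if (length(qi) == 0L) next
    inside[qi] <- .in_intervals(pos[qi], sub$start, sub$end)
  }
  inside
}

#' Distances between consecutive RT peaks
#'
#' Distances are taken between consecutive peaks within the same segment.
#' When `regions` is given, a distance is attributed to the region set iff
#' both peaks lie inside region intervals (use `invert = TRUE` for the
#' complement, i.e. "rest of the genome").
#'
#' @param extrema Output of [call_extrema()].
#' @param regions Optional interval `data.frame` (`chrom`, `start`, `end`).
#' @param invert Attribute distances whose peaks both lie *outside* the
#'   regions instead.
#' @return List with `distances` (bp) and their `median`.
#' @export
inter_peak_distances <- function(extrema, regions = NULL, invert = FALSE) {
  pk <- extrema[extrema$kind == "peak", , drop = FALSE]
  dist <- numeric(0)
  for (s in unique(pk$segment_id)) {
    sub <- pk[pk$segment_id == s, , drop = FALSE]
    if (nrow(sub) < 2L) next
    keep <- rep(TRUE, nrow(sub) - 1L)
    if (!is.null(regions)) {
      inside <- .points_in_regions(sub$chrom, sub$position, regions)
      if (invert) inside <- !inside
      keep <- inside[-nrow(sub)] & inside[-1L]
    }
    dist <- c(dist, diff(sub$position)[keep])
  }
  list(distances = dist,
       median = if (length(dist)) stats::median(dist) else NA_real_)
}

#' Slopes of RT peaks
#'
#' For each peak, the ascending slope is `|rt_peak - rt_left_valley|`
#' divided by the distance to the left valley (in Mb), the descending slope
#' the analog on the right; the peak's slope is their average. A peak
#' without a valley neighbor on one side (segment edge) anchors that side
#' at the segment's boundary bin instead; if the boundary coincides with
#' the peak the side is dropped and the single available side is used.
#' Units: z-units per Mb.
#'
#' @param profile The `"rt_profile"` the extrema were called from (supplies
#'   segment boundary bins for edge peaks).
#' @inheritParams inter_peak_distances
#' @return List with `slopes` (`data.frame`: `chrom`, `position`,
#'   `ascending`, `descending`, `slope`) and the `median` slope.
#' @export
peak_slopes <- function(profile, extrema, regions = NULL, invert = FALSE) {
  parts <- list()
  for (s in unique(extrema$segment_id)) {
    sub <- extrema[extrema$segment_id == s, , drop = FALSE]
    seg <- profile[profile$segment_id == s, , drop = FALSE]
    first <- list(position = seg$center[1L], rt = seg$rt[1L])
    last <- list(position = seg$center[nrow(seg)], rt = seg$rt[nrow(seg)])
    pk_idx <- which(sub$kind == "peak")
    for (i in pk_idx) {
      left <- if (i > 1L) list(position = sub$position[i - 1L],
                               rt = sub$rt[i - 1L]) else first
      right <- if (i < nrow(sub)) list(position = sub$position[i + 1L],
                                       rt = sub$rt[i + 1L]) else last
      asc <- if (left$position < sub$position[i])
        abs(sub$rt[i] - left$rt) /
          ((sub$position[i] - left$position) / 1e6) else NA_real_
      dsc <- if (right$position > sub$position[i])
        abs(sub$rt[i] - right$rt) /
          ((right$position - sub$position[i]) / 1e6) else NA_real_
      if (is.na(asc) && is.na(dsc)) next
      parts[[length(parts) + 1L]] <- data.frame(
        chrom = sub$chrom[i], position = sub$position[i],
        ascending = asc, descending = dsc,
        slope = mean(c(asc, dsc), na.rm = TRUE), stringsAsFactors = FALSE)
    }
  }
  slopes <- if (length(parts)) do.call(rbind, parts)
            else data.frame(chrom = character(0), position = numeric(0),
                            ascending = numeric(0), descending = numeric(0),
                            slope = numeric(0))
  if (!is.null(regions) && nrow(slopes)) {
    inside <- .points_in_regions(slopes$chrom, slopes$position, regions)
    if (invert) inside <- !inside
    slopes <- slopes[inside, , drop = FALSE]
  }
  rownames(slopes) <- NULL
  list(slopes = slopes,
       median = if (nrow(slopes)) stats::median(slopes$slope) else NA_real_)
}

#' Replication dynamics summary
#'
#' Inter-peak distances and peak slopes genome-wide (outside the
#' centromeric regions when given, matching "rest of the genome"), inside
#' centromeric regions, and inside HOR arrays.
#'
#' @param profile An `"rt_profile"`.
#' @param regions Optional centromeric-region intervals.
#' @param hor Optional HOR-array intervals.
#' @param min_prominence Passed to [call_extrema()].
#' @return List with `extrema` and one `list(distances, slopes,
#'   median_distance, median_slope)` per scope (`genome`, `centromere`,
#'   `hor` as available).
#' @export
replication_dynamics <- function(profile, regions = NULL, hor = NULL,
                                 min_prominence = 0) {
  ex <- call_extrema(profile, min_prominence)
  scope <- function(reg, invert = FALSE) {
    d <- inter_peak_distances(ex, reg, invert)
    s <- peak_slopes(profile, ex, reg, invert)
    list(distances = d$distances, slopes = s$slopes,
         median_distance = d$median, median_slope = s$median)
  }
  out <- list(extrema = ex,
              genome = scope(regions, invert = !is.null(regions)))
  if (!is.null(regions)) out$centromere <- scope(regions)
  if (!is.null(hor)) out$hor <- scope(hor)
  out
}
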