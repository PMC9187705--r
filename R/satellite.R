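# Satellite-family replication timing bias: intersect profile bins with a
# cenSat-style annotation and summarize per-family RT distributions.

#' Assign profile bins to annotation families
#'
#' A bin belongs to the family whose interval covers its center (half-open:
#' a center exactly on a boundary belongs to the interval starting there).
#' Bins with uncovered centers get NA. The annotation must be a partition:
#' overlapping intervals of different families are an error (same-family
#' overlaps are merged).
#'
#' @param profile An `"rt_profile"`.
#' @param annotation Interval `data.frame` with columns `chrom`, `start`,
#'   `end`, `family` (see [read_censat()]).
#' @return Character vector of family labels, one per profile bin (NA =
#'   unannotated).
#' @export
assign_bins_to_families <- function(profile, annotation) {
  stopifnot(all(c("chrom", "start", "end", "family") %in% names(annotation)))
  fam <- rep(NA_character_, nrow(profile))
  for (ch in unique(annotation$chrom)) {
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    ann <- ann[order(ann$start, ann$end), , drop = FALSE]
    if (nrow(ann) > 1L) {
      ov <- which(ann$start[-1L] < ann$end[-nrow(ann)])
      if (any(ann$family[ov] != ann$family[ov + 1L]))
        stop(sprintf("overlapping annotation intervals of different families on %s",
                     ch))
      # merge same-family overlaps so lookup stays well defined
      while (length(ov <- which(ann$start[-1L] < ann$end[-nrow(ann)]))) {
        i <- ov[1L]
        ann$end[i] <- max(ann$end[i], ann$end[i + 1L])
        ann <- ann[-(i + 1L), , drop = FALSE]
        if (nrow(ann) < 2L) break
      }
    }
    qi <- which(profile$chrom == ch)
    if (length(qi) == 0L) next
    idx <- findInterval(profile$center[qi], ann$start)
    hit <- idx > 0L & profile$center[qi] < ann$end[pmax(idx, 1L)]
    fam[qi[hit]] <- ann$family[idx[hit]]
  }
  fam
}

#' Per-family replication timing statistics
#'
#' Median, interquartile range, early fraction (share of bins with rt > 0)
#' and bin count per family, plus the same statistics over a baseline bin
#' subset (e.g. all non-centromeric bins).
#'
#' @param profile An `"rt_profile"`.
#' @param families Family label per bin (from
#'   [assign_bins_to_families()]).
#' @param baseline Logical vector selecting the baseline bins.
#' @return `data.frame` with one row per family (label `"baseline"` for the
#'   baseline subset) and columns `family`, `n_bins`, `median`, `iqr`,
#'   `early_fraction`.
#' @export
family_stats <- function(profile, families, baseline) {
  stopifnot(length(families) == nrow(profile),
            length(baseline) == nrow(profile))
  if (!any(baseline)) stop("empty baseline")
  one <- function(label, rt) data.frame(
    family = label, n_bins = length(rt), median = stats::median(rt),
    iqr = stats::IQR(rt), early_fraction = mean(rt > 0),
    stringsAsFactors = FALSE)
  labs <- sort(unique(families[!is.na(families)]))
  rows <- lapply(labs, function(f) one(f, profile$rt[!is.na(families) &
                                                       families == f]))
  out <- rbind(do.call(rbind, rows), one("baseline", profile$rt[baseline]))
  rownames(out) <- NULL
  out
}

#' Early replication within newly resolved regions, by family
#'
#' Among bins inside `regions` with rt > 0 ("early"), the fraction assigned
#' to each annotation family (unannotated bins are reported as
#' `"unlabeled"`). Fractions sum to 1 when any early bin exists.
#'
#' @param profile An `"rt_profile"`.
#' @param regions Interval `data.frame` (`chrom`, `start`, `end`).
#' @param annotation Family annotation (see
#'   [assign_bins_to_families()]).
#' @return List with `n_bins` (bins inside the regions), `n_early`, and
#'   `shares` (`data.frame`: `family`, `n_early`, `share`).
#' @export
newly_resolved_summary <- function(profile, regions, annotation) {
  inside <- .points_in_regions(profile$chrom, profile$center, regions)
  fam <- assign_bins_to_families(profile, annotation)
  fam[is.na(fam)] <- "unlabeled"
  early <- inside & profile$rt > 0
  tab <- table(fam[early])
  shares <- data.frame(family = names(tab), n_early = as.integer(tab),
                       share = if (sum(tab)) as.numeric(tab) / sum(tab)
                               else numeric(length(tab)),
                       stringsAsFactors = FALSE)
  rownames(shares) <- NULL
  list(n_bins = sum(inside), n_early = sum(early), shares = shares)
}

#' Satellite RT-bias analysis
#'
#' Convenience wrapper: assigns bins to families and computes
#' [family_stats()] with the baseline defaulting to all bins outside the
#' centromeric regions.
#'
#' @param profile An `"rt_profile"`.
#' @param annotation Family annotation intervals.
#' @param centromeres Optional centromeric intervals; baseline = bins
#'   outside them (all bins when NULL).
#' @return List with `families` (per-bin labels) and `stats`
#'   (see [family_stats()]).
#' @export
satellite_rt <- function(profile, annotation, centromeres = NULL) {
  fam <- assign_bins_to_families(profile, annotation)
  baseline <- if (is.null(centromeres)) rep(TRUE, nrow(profile))
              else !.points_in_regions(profile$chrom, profile$center,
                                       centromeres)
  list(families = fam, stats = family_stats(profile, fam, baseline))
}
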