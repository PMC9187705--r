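# UCSC chain parsing and fixed-width window mapping between assemblies,
# plus cross-build profile correlation. The mapping rule is deliberately
# simpler than full liftOver: each window maps through the single
# highest-scoring overlapping chain iff at least `min_match` of its bases
# fall in aligned blocks of that chain.

#' Parse a UCSC chain file
#'
#' Validates block arithmetic on both sides (`sum(size) + sum(dt)` must
#' equal the declared target span, query analog) and returns chains ordered
#' by score, descending.
#'
#' @param path Chain file path.
#' @return List of class `"chain_set"`; each chain holds the header fields
#'   (`score`, `t_name`, `t_size`, `t_strand`, `t_start`, `t_end`,
#'   `q_name`, `q_size`, `q_strand`, `q_start`, `q_end`, `id`) and a
#'   `blocks` `data.frame` (`size`, `dt`, `dq`).
#' @export
parse_chain <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12L)
      stop(sprintf("malformed chain header at line %d", i))
    hdr <- list(score = as.numeric(f[2]),
                t_name = f[3], t_size = as.numeric(f[4]), t_strand = f[5],
                t_start = as.numeric(f[6]), t_end = as.numeric(f[7]),
                q_name = f[8], q_size = as.numeric(f[9]), q_strand = f[10],
                q_start = as.numeric(f[11]), q_end = as.numeric(f[12]),
                id = if (length(f) >= 13L) f[13] else NA_character_)
    if (!hdr$t_strand %in% "+" || !hdr$q_strand %in% c("+", "-"))
      stop(sprintf("unsupported strand in chain %s", hdr$id))
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    repeat {
      i <- i + 1L
      if (i > length(lines)) stop("truncated chain file")
      b <- as.numeric(strsplit(lines[i], "[ \t]+")[[1]])
      if (length(b) == 1L) {
        sizes <- c(sizes, b); dts <- c(dts, 0); dqs <- c(dqs, 0)
        i <- i + 1L
        break
      }
      if (length(b) != 3L) stop(sprintf("malformed block line %d", i))
      sizes <- c(sizes, b[1]); dts <- c(dts, b[2]); dqs <- c(dqs, b[3])
    }
    if (sum(sizes) + sum(dts) != hdr$t_end - hdr$t_start ||
        sum(sizes) + sum(dqs) != hdr$q_end - hdr$q_start)
      stop(sprintf("chain block arithmetic mismatch (chain id %s)",
                   if (is.na(hdr$id)) "?" else hdr$id))
    hdr$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    chains[[length(chains) + 1L]] <- hdr
  }
  chains <- chains[order(vapply(chains, `[[`, numeric(1), "score"),
                         decreasing = TRUE)]
  structure(chains, class = "chain_set")
}

# Absolute block coordinates of one chain (target side and raw query side).
.chain_blocks <- function(chain) {
  b <- chain$blocks
  t0 <- chain$t_start + cumsum(c(0, (b$size + b$dt)[-nrow(b)]))
  q0 <- chain$q_start + cumsum(c(0, (b$size + b$dq)[-nrow(b)]))
  data.frame(t_start = t0, t_end = t0 + b$size,
             q_start = q0, q_end = q0 + b$size)
}

#' Tile a genome into fixed-width windows
#'
#' @param genome Genome descriptor ([genome_descriptor()]).
#' @param width Window width in bp (default 1 kb); the terminal window of a
#'   chromosome may be shorter.
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
tile_genome <- function(genome, width = 1000) {
  parts <- lapply(seq_len(nrow(genome)), function(i) {
    start <- seq(0, genome$length[i] - 1, by = width)
    data.frame(chrom = genome$chrom[i], start = start,
               end = pmin(start + width, genome$length[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Map fixed-width windows through a chain set
#'
#' Each window maps through the single highest-scoring chain overlapping it
#' on the target (source) side, and is mapped iff at least `min_match` of
#' its bases fall in aligned blocks of that chain. Negative-strand query
#' coordinates are converted to forward-strand intervals. Unmapped reasons:
#' `no_chain` (no overlapping chain), `partial` (aligned fraction below
#' `min_match`), `split` (enough aligned bases, but they span an internal
#' indel so large that the query span is inconsistent with a single
#' interval).
#'
#' @param windows Window `data.frame` (`chrom`, `start`, `end`), e.g. from
#'   [tile_genome()].
#' @param chains A `"chain_set"` from [parse_chain()].
#' @param min_match Minimum aligned-base fraction (default 0.95).
#' @return `data.frame`: windows plus `mapped`, `reason`, `match_frac`,
#'   `q_chrom`, `q_start`, `q_end` (forward strand).
#' @export
map_windows <- function(windows, chains, min_match = 0.95) {
  stopifnot(min_match > 0, min_match <= 1)
  blocks <- lapply(chains, .chain_blocks)
  n <- nrow(windows)
  mapped <- logical(n)
  reason <- rep(NA_character_, n)
  frac <- numeric(n)
  q_chrom <- rep(NA_character_, n)
  q_start <- rep(NA_real_, n)
  q_end <- rep(NA_real_, n)
  for (w in seq_len(n)) {
    ws <- windows$start[w]; we <- windows$end[w]
    width <- we - ws
    ci <- which(vapply(chains, function(ch)
      ch$t_name == windows$chrom[w] && ch$t_start < we && ch$t_end > ws,
      logical(1)))
    if (length(ci) == 0L) { reason[w] <- "no_chain"; next }
    ci <- ci[1L]                       # chains are score-sorted
    bl <- blocks[[ci]]
    ov <- pmax(0, pmin(we, bl$t_end) - pmax(ws, bl$t_start))
    aligned <- sum(ov)
    frac[w] <- aligned / width
    if (frac[w] < min_match) { reason[w] <- "partial"; next }
    j <- which(ov > 0)
    j1 <- j[1L]; j2 <- j[length(j)]
    q_lo <- bl$q_start[j1] + (max(ws, bl$t_start[j1]) - bl$t_start[j1])
    q_hi <- bl$q_start[j2] + (min(we, bl$t_end[j2]) - bl$t_start[j2])
    if ((q_hi - q_lo) - aligned > (1 - min_match) * width) {
      reason[w] <- "split"; next
    }
    ch <- chains[[ci]]
    if (ch$q_strand == "-") {
      tmp <- ch$q_size - q_hi
      q_hi <- ch$q_size - q_lo
      q_lo <- tmp
    }
    mapped[w] <- TRUE
    q_chrom[w] <- ch$q_name
    q_start[w] <- q_lo
    q_end[w] <- q_hi
  }
  out <- cbind(windows,
               data.frame(mapped = mapped, reason = reason,
                          match_frac = frac, q_chrom = q_chrom,
                          q_start = q_start, q_end = q_end,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Mapped/unmapped accounting of a window map
#'
#' @param window_map Output of [map_windows()].
#' @return List with `mapped_fraction`, `unmapped_fraction` (summing to 1
#'   exactly) and a `by_reason` table.
#' @export
map_fractions <- function(window_map) {
  n <- nrow(window_map)
  m <- sum(window_map$mapped)
  list(mapped_fraction = m / n, unmapped_fraction = (n - m) / n,
       by_reason = table(window_map$reason[!window_map$mapped]))
}

#' Correlate two profiles across assemblies
#'
#' Pearson correlation of rt values evaluated (nearest bin within
#' `max_gap`) at mapped window midpoints: source midpoints in `profile_a`,
#' mapped query midpoints in `profile_b`.
#'
#' @param profile_a,profile_b `"rt_profile"` objects on the source and
#'   target assemblies.
#' @param window_map Output of [map_windows()].
#' @param max_gap Maximum bin-center distance for evaluation (bp).
#' @return List with `r` (Pearson) and `n` (paired windows used).
#' @export
profile_correlation <- function(profile_a, profile_b, window_map,
                                max_gap = 1e5) {
  wm <- window_map[window_map$mapped, , drop = FALSE]
  ra <- profile_at(profile_a, wm$chrom, (wm$start + wm$end) / 2, max_gap)
  rb <- profile_at(profile_b, wm$q_chrom, (wm$q_start + wm$q_end) / 2,
                   max_gap)
  ok <- !is.na(ra) & !is.na(rb)
  if (sum(ok) < 3L) stop("fewer than 3 paired points")
  list(r = stats::cor(ra[ok], rb[ok]), n = sum(ok))
}
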