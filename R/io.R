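# Readers and writers for the plain-text genomics formats the pipeline
# touches: BED3/BED9, bedGraph, two-column chrom.sizes. All coordinates are
# 0-based half-open internally; any 1-based dialect conversion happens only
# at the boundary (none of the supported formats needs one).

#' Is a chromosome name an autosome?
#'
#' Recognizes `chr1..chr22` and bare `1..22` (case-insensitive). The X
#' chromosome is kept but never contributes to normalization statistics;
#' Y is dropped from profiles.
#'
#' @param chrom Character vector of chromosome names.
#' @return Logical vector.
#' @export
is_autosome <- function(chrom) {
  grepl("^(chr)?([1-9]|1[0-9]|2[0-2])$", chrom, ignore.case = TRUE)
}

.is_chrx <- function(chrom) grepl("^(chr)?x$", chrom, ignore.case = TRUE)
.is_chry <- function(chrom) grepl("^(chr)?y$", chrom, ignore.case = TRUE)

#' Construct a genome descriptor
#'
#' @param chrom Unique chromosome names.
#' @param length Chromosome lengths in bp (> 0).
#' @return `data.frame` with columns `chrom`, `length`, `autosome`.
#' @export
genome_descriptor <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length) | length <= 0))
    stop("chromosome lengths must be positive")
  data.frame(chrom = chrom, length = length, autosome = is_autosome(chrom),
             stringsAsFactors = FALSE)
}

#' Read a chrom.sizes file
#'
#' @param path Two-column text file: chromosome name, length.
#' @return A genome descriptor (see [genome_descriptor()]).
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom.sizes must have two columns")
  genome_descriptor(df[[1]], df[[2]])
}

#' Read a BED file
#'
#' Reads BED3+ intervals (or read starts), validates coordinates, and
#' returns them sorted by chromosome then start.
#'
#' @param path BED file path (tab-separated, 0-based half-open, no header).
#' @param genome Optional genome descriptor for coordinate validation.
#' @param unknown What to do with records on chromosomes absent from
#'   `genome`: `"fail"` (default) or `"skip"` (dropped with a message).
#' @return `data.frame` with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`. Attribute `"n_skipped"` counts
#'   skipped records.
#' @export
read_bed <- function(path, genome = NULL, unknown = c("fail", "skip")) {
  unknown <- match.arg(unknown)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          fill = TRUE)
  if (ncol(df) < 3) stop("BED file must have at least 3 columns")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df)[seq_len(min(ncol(df), 6L))] <- cols[seq_len(min(ncol(df), 6L))]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  line <- seq_len(nrow(df))
  if (any(bad <- df$start == df$end))
    stop(sprintf("empty interval at line %d", line[bad][1]))
  if (any(bad <- !is.finite(df$start) | !is.finite(df$end) |
            df$start < 0 | df$start > df$end))
    stop(sprintf("invalid interval at line %d", line[bad][1]))
  n_skipped <- 0L
  if (!is.null(genome)) {
    known <- df$chrom %in% genome$chrom
    if (!all(known)) {
      if (unknown == "fail")
        stop(sprintf("unknown chromosome '%s' at line %d",
                     df$chrom[!known][1], line[!known][1]))
      n_skipped <- sum(!known)
      message(sprintf("read_bed: skipped %d record(s) on unknown chromosomes",
                      n_skipped))
      df <- df[known, , drop = FALSE]
      line <- line[known]
    }
    len <- genome$length[match(df$chrom, genome$chrom)]
    if (any(bad <- df$end > len))
      stop(sprintf("coordinate beyond chromosome end at line %d",
                   line[bad][1]))
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  message(sprintf("read_bed: %d record(s) from %s", nrow(df), path))
  attr(df, "n_skipped") <- n_skipped
  df
}

#' Write intervals or reads as BED3
#'
#' @param x `data.frame` with `chrom`, `start`, `end`, or a read set with
#'   `chrom`, `pos` (written as 1-bp intervals).
#' @param path Output path.
#' @export
write_bed3 <- function(x, path) {
  if (!is.null(x$pos) && is.null(x$start)) {
    x <- data.frame(chrom = x$chrom, start = x$pos, end = x$pos + 1)
  }
  lines <- sprintf("%s\t%.0f\t%.0f", x$chrom, x$start, x$end)
  writeLines(lines, path)
  invisible(path)
}

#' Default cenSat-name prefix table
#'
#' Ordered, case-insensitive prefix -> family map in the
#' "cenSatAnnotation" dialect. `dhor` must precede `hor`; `censat` itself
#' maps to the catch-all class. Override by passing a modified copy to
#' [parse_censat_name()].
#'
#' @return Named character vector: names are lower-case prefixes, values
#'   canonical family labels.
#' @export
censat_family_table <- function() {
  c(dhor = "dhor", hor = "hor", mon = "mon",
    hsat1 = "hsat1", hsat2 = "hsat2", hsat3 = "hsat3",
    bsat = "bsat", gsat = "gsat", rdna = "rDNA",
    ct = "ct", censat = "censat_other")
}

#' Map cenSat annotation names to canonical satellite families
#'
#' Case-insensitive prefix matching against [censat_family_table()];
#' unrecognized names fall back to `"censat_other"` with a warning. Total:
#' never errors on a non-empty name.
#'
#' @param name Character vector of raw annotation names (e.g. `"ct_1"`,
#'   `"HSat3_weird_suffix"`).
#' @param table Prefix table, by default [censat_family_table()].
#' @return Character vector of family labels.
#' @export
parse_censat_name <- function(name, table = censat_family_table()) {
  if (any(!nzchar(name))) stop("annotation names must be non-empty")
  low <- tolower(name)
  fam <- rep(NA_character_, length(name))
  for (pfx in names(table)) {
    hit <- is.na(fam) & startsWith(low, pfx)
    fam[hit] <- table[[pfx]]
  }
  if (any(is.na(fam))) {
    warning(sprintf("unrecognized cenSat name(s) mapped to censat_other: %s",
                    paste(unique(name[is.na(fam)]), collapse = ", ")))
    fam[is.na(fam)] <- "censat_other"
  }
  fam
}

#' Read a cenSat-style BED9 annotation
#'
#' @inheritParams read_bed
#' @param table Prefix table for [parse_censat_name()].
#' @return Interval `data.frame` with an added `family` column.
#' @export
read_censat <- function(path, genome = NULL, unknown = c("fail", "skip"),
                        table = censat_family_table()) {
  df <- read_bed(path, genome, unknown)
  if (is.null(df$name)) stop("cenSat annotation requires a name column (BED4+)")
  df$family <- parse_censat_name(df$name, table)
  df
}

#' Write a bedGraph track
#'
#' Fixed 6-decimal value formatting; write-then-read reproduces values to
#' within 1e-6.
#'
#' @param x `data.frame` with columns `chrom`, `start`, `end` and a value
#'   column; bins must be sorted and non-overlapping within chromosomes.
#' @param path Output path.
#' @param value_col Name of the value column (default `"value"`).
#' @export
write_bedgraph <- function(x, path, value_col = "value") {
  if (nrow(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "start", "end", value_col) %in% names(x)))
  for (ch in unique(x$chrom)) {
    sub <- x[x$chrom == ch, , drop = FALSE]
    if (is.unsorted(sub$start) ||
        any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping or unsorted bins in bedGraph output")
  }
  writeLines(sprintf("%s\t%.0f\t%.0f\t%.6f",
                     x$chrom, x$start, x$end, x[[value_col]]), path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `value`
#'   (empty if the file is empty).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  df <- utils::read.table(text = lines, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df[1:4], c("chrom", "start", "end", "value"))
}

#' Read sorted read start positions from BED3
#'
#' Uses the interval start as the read start position (fragment lengths are
#' ignored throughout the pipeline).
#'
#' @inheritParams read_bed
#' @return `data.frame` with columns `chrom`, `pos`, sorted.
#' @export
read_reads_bed <- function(path, genome = NULL, unknown = c("fail", "skip")) {
  df <- read_bed(path, genome, unknown)
  data.frame(chrom = df$chrom, pos = df$start, stringsAsFactors = FALSE)
}
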