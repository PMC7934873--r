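# Plain-text genomics IO: FASTA (via Biostrings), BED6, bedGraph, chrom.sizes.
#
# All interval coordinates follow the BED convention: 0-based, half-open
# [start, end). bedGraph files for the minus strand store magnitudes
# (positive values); strand is encoded by which file an interval lives in.

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stopf("`sequences` must be a named character vector")
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Read a chrom.sizes file
#'
#' Two tab- or space-delimited columns: chromosome name, length in bases.
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "size"))
  if (!is.numeric(tab$size) || any(tab$size <= 0))
    stopf("chromosome sizes must be positive numbers in %s", path)
  stats::setNames(as.integer(tab$size), tab$chrom)
}

#' Write motif instances or intervals as BED6
#'
#' Expects a data frame with columns `chrom`, `start`, `end`, and optionally
#' `name` (or `motif_id`), `score`, `strand`. Scores are written as
#' `round(score * 100)` per the BED integer-score convention.
#'
#' @param x Data frame of intervals (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  name <- x$name %||% x$motif_id %||% rep(".", nrow(x))
  score <- x$score %||% rep(0, nrow(x))
  strand <- x$strand %||% rep(".", nrow(x))
  out <- data.frame(x$chrom, x$start, x$end, name,
                    as.integer(round_half_up(score * 100)), strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of motif instances
#'
#' Inverse of [write_bed()]: the name column is interpreted as `motif_id`
#' and the score column is divided by 100 to recover bit scores.
#'
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `score`, `motif_id`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stopf("%s: BED needs at least 3 columns", path)
  data.frame(
    chrom = as.character(tab[[1L]]),
    start = as.integer(tab[[2L]]),
    end = as.integer(tab[[3L]]),
    strand = if (ncol(tab) >= 6L) as.character(tab[[6L]]) else ".",
    score = if (ncol(tab) >= 5L) as.numeric(tab[[5L]]) / 100 else 0,
    motif_id = if (ncol(tab) >= 4L) as.character(tab[[4L]]) else ".",
    stringsAsFactors = FALSE
  )
}

# Run-length encode one coverage vector into bedGraph rows (nonzero runs only).
.coverage_to_bedgraph <- function(counts, chrom) {
  r <- rle(as.numeric(counts))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             value = r$values[keep], stringsAsFactors = FALSE)
}

#' Write strand-specific coverage as a pair of bedGraph files
#'
#' Minus-strand counts are written as positive magnitudes in their own file.
#'
#' @param cov A `strand_coverage` object (see [strand_coverage()]).
#' @param plus_path,minus_path Output paths for the two strands.
#' @return Character vector of the two paths, invisibly.
#' @export
write_bedgraph <- function(cov, plus_path, minus_path) {
  stopifnot(inherits(cov, "strand_coverage"))
  for (side in c("plus", "minus")) {
    path <- if (side == "plus") plus_path else minus_path
    rows <- do.call(rbind, lapply(names(cov[[side]]), function(chrom)
      .coverage_to_bedgraph(cov[[side]][[chrom]], chrom)))
    if (is.null(rows))
      rows <- data.frame(chrom = character(), start = integer(),
                         end = integer(), value = numeric())
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(plus_path, minus_path))
}
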