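# Bidirectional eRNA origin calling from strand-specific nascent coverage.
#
# An eRNA origin is the center of a divergent ("bidirectional") signature:
# minus-strand signal immediately upstream paired with plus-strand signal
# immediately downstream, as produced by RNA polymerase II loading at an
# active enhancer. The published mixture-model callers are replaced here by
# a deterministic smooth -> peak -> pair -> merge rule, which is all the
# motif displacement analysis needs from this stage: origin points.

#' Strand-specific coverage container
#'
#' @param plus,minus Named lists of nonnegative count vectors, one per
#'   chromosome, sharing names and lengths. Vector index `i` holds the
#'   count at 0-based genomic position `i - 1`.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return An object of class `strand_coverage`.
#' @export
strand_coverage <- function(plus, minus, chrom_sizes) {
  if (!identical(sort(names(plus)), sort(names(chrom_sizes))) ||
      !identical(sort(names(minus)), sort(names(chrom_sizes))))
    stopf("`plus`, `minus` and `chrom_sizes` must cover the same chromosomes")
  for (chrom in names(chrom_sizes)) {
    for (side in list(plus, minus)) {
      v <- side[[chrom]]
      if (length(v) != chrom_sizes[[chrom]])
        stopf("coverage length for %s (%d) does not match chromosome size (%d)",
              chrom, length(v), chrom_sizes[[chrom]])
      if (any(v < 0)) stopf("negative coverage on %s", chrom)
    }
  }
  structure(list(plus = plus, minus = minus,
                 chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                               names(chrom_sizes))),
            class = "strand_coverage")
}

#' @export
print.strand_coverage <- function(x, ...) {
  cat(sprintf("<strand_coverage> %d chromosome(s); %s plus / %s minus reads\n",
              length(x$chrom_sizes),
              format(sum(vapply(x$plus, sum, 0))),
              format(sum(vapply(x$minus, sum, 0)))))
  invisible(x)
}

# Parse one bedGraph file into per-chromosome dense vectors.
.read_bedgraph_dense <- function(path, chrom_sizes) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(track|browser|#)", trimws(lines)))
  arrays <- lapply(chrom_sizes, function(n) numeric(n))
  touched <- lapply(chrom_sizes, function(n) logical(n))  # for overlap check
  for (ln in keep) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(f) < 4L)
      stopf("%s line %d: bedGraph needs 4 columns", path, ln)
    chrom <- f[1L]
    if (!chrom %in% names(chrom_sizes))
      stopf("%s line %d: unknown chromosome '%s'", path, ln, chrom)
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    value <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(start) || is.na(end) || is.na(value) || start < 0 ||
        end <= start)
      stopf("%s line %d: malformed interval", path, ln)
    if (end > chrom_sizes[[chrom]])
      stopf("%s line %d: interval [%d, %d) exceeds %s length %d",
            path, ln, start, end, chrom, chrom_sizes[[chrom]])
    if (value < 0)
      stopf("%s line %d: negative value %g (minus-strand files store magnitudes)",
            path, ln, value)
    idx <- (start + 1L):end
    if (any(touched[[chrom]][idx]))
      stopf("%s line %d: interval [%d, %d) overlaps an earlier interval on %s",
            path, ln, start, end, chrom)
    touched[[chrom]][idx] <- TRUE
    arrays[[chrom]][idx] <- value
  }
  arrays
}

#' Read strand-specific coverage from a pair of bedGraph files
#'
#' The minus-strand file must store magnitudes (positive values). Intervals
#' are 0-based half-open; overlapping intervals within a file are an error.
#'
#' @param plus_bedgraph,minus_bedgraph bedGraph file paths.
#' @param chrom_sizes Named integer vector, or path to a chrom.sizes file.
#' @return A [strand_coverage()] object.
#' @export
read_strand_coverage <- function(plus_bedgraph, minus_bedgraph, chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L &&
      is.null(names(chrom_sizes)))
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  strand_coverage(plus = .read_bedgraph_dense(plus_bedgraph, chrom_sizes),
                  minus = .read_bedgraph_dense(minus_bedgraph, chrom_sizes),
                  chrom_sizes = chrom_sizes)
}

#' Construct an eRNA origin set
#'
#' @param df Data frame with at least `chrom` and `origin` (0-based
#'   position); optional peak metadata columns `minus_peak`, `plus_peak`,
#'   `minus_mass`, `plus_mass`.
#' @return The data frame with class `origin_set` prepended.
#' @export
origin_set <- function(df) {
  stopifnot(all(c("chrom", "origin") %in% names(df)))
  for (col in c("minus_peak", "plus_peak", "minus_mass", "plus_mass"))
    if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, nrow(df))
  if (any(!is.na(df$minus_peak) & !is.na(df$plus_peak) &
            (df$minus_peak > df$origin | df$origin > df$plus_peak)))
    stopf("origin must lie between its minus and plus peaks")
  class(df) <- c("origin_set", "data.frame")
  df
}

# Zero-padded centered moving sum with halfwidth h (window 2h + 1).
.moving_sum <- function(x, halfwidth) {
  n <- length(x)
  h <- as.integer(halfwidth)
  cs <- cumsum(c(0, x))
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1L)
  cs[hi + 1L] - cs[lo]
}

# Local maxima of a smoothed track with value >= min_value, as 1-based
# indices. A maximal plateau (run of equal values higher than both
# neighbors) collapses to its center position, floor on even lengths so
# ties break toward the smaller coordinate. A smoothed point source is a
# plateau whose center is the source position.
.local_maxima <- function(x, min_value) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  left <- c(-Inf, x[-n])
  starts <- which(x > left & x >= min_value)  # plateau start candidates
  if (!length(starts)) return(integer(0))
  out <- integer(0)
  for (i in starts) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # end of plateau
    if ((j == n) || (x[j + 1L] < x[i]))
      out <- c(out, (i + j) %/% 2L)
  }
  out
}

#' Call bidirectional eRNA origins from strand-specific coverage
#'
#' Procedure: (1) each strand is smoothed with a centered moving sum of
#' halfwidth `smoothing_halfwidth`; (2) strand-local maxima with smoothed
#' mass at least `min_reads` are located (plateau ties break toward the
#' smaller coordinate); (3) each minus-strand maximum is paired with the
#' nearest downstream plus-strand maximum when
#' `0 < plus_peak - minus_peak <= max_separation`, one-to-one greedily by
#' descending total smoothed mass; (4) the origin is the rounded
#' mass-weighted mean of the two peak positions; (5) origins closer than
#' `merge_distance` are merged keeping the higher total mass, ties toward
#' the smaller coordinate.
#'
#' @param cov A [strand_coverage()] object.
#' @param min_reads Minimum smoothed mass for a peak.
#' @param max_separation Maximum minus-to-plus peak distance (bases).
#' @param smoothing_halfwidth Moving-sum halfwidth (bases).
#' @param merge_distance Origins closer than this are merged (bases).
#' @return An [origin_set()] with peak positions and smoothed masses;
#'   zero rows when no divergent pair is found.
#' @export
call_origins <- function(cov, min_reads = 20, max_separation = 300,
                         smoothing_halfwidth = 30, merge_distance = 150) {
  stopifnot(inherits(cov, "strand_coverage"))
  for (v in c(min_reads, max_separation, smoothing_halfwidth, merge_distance))
    if (!is_number(v) || v <= 0) stopf("caller parameters must be positive")

  rows <- list()
  for (chrom in names(cov$chrom_sizes)) {
    sp <- .moving_sum(cov$plus[[chrom]], smoothing_halfwidth)
    sm <- .moving_sum(cov$minus[[chrom]], smoothing_halfwidth)
    plus_pk <- .local_maxima(sp, min_reads)    # 1-based indices
    minus_pk <- .local_maxima(sm, min_reads)
    if (!length(plus_pk) || !length(minus_pk)) next

    # candidate pair per minus peak: nearest strictly-downstream plus peak
    nxt <- findInterval(minus_pk, plus_pk) + 1L
    ok <- nxt <= length(plus_pk)
    cand_m <- minus_pk[ok]
    cand_p <- plus_pk[nxt[ok]]
    sep <- cand_p - cand_m
    ok2 <- sep > 0 & sep <= max_separation
    cand_m <- cand_m[ok2]; cand_p <- cand_p[ok2]
    if (!length(cand_m)) next
    mass_m <- sm[cand_m]; mass_p <- sp[cand_p]
    total <- mass_m + mass_p
    ord <- order(-total, cand_m)
    used_m <- integer(0); used_p <- integer(0)
    sel <- integer(0)
    for (i in ord) {
      if (cand_m[i] %in% used_m || cand_p[i] %in% used_p) next
      used_m <- c(used_m, cand_m[i]); used_p <- c(used_p, cand_p[i])
      sel <- c(sel, i)
    }
    origin <- round_half_up((mass_m[sel] * cand_m[sel] +
                               mass_p[sel] * cand_p[sel]) /
                              (mass_m[sel] + mass_p[sel]))
    rows[[chrom]] <- data.frame(
      chrom = chrom,
      origin = as.integer(origin) - 1L,        # back to 0-based
      minus_peak = cand_m[sel] - 1L, plus_peak = cand_p[sel] - 1L,
      minus_mass = mass_m[sel], plus_mass = mass_p[sel],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(origin_set(data.frame(chrom = character(), origin = integer(),
                                 minus_peak = integer(), plus_peak = integer(),
                                 minus_mass = numeric(), plus_mass = numeric(),
                                 stringsAsFactors = FALSE)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  # merge nearby origins per chromosome, keeping the higher total mass
  merged <- lapply(split(res, res$chrom), function(d) {
    total <- d$minus_mass + d$plus_mass
    ord <- order(-total, d$origin)
    accepted <- integer(0)
    for (i in ord) {
      if (!length(accepted) ||
          all(abs(d$origin[accepted] - d$origin[i]) >= merge_distance))
        accepted <- c(accepted, i)
    }
    d[sort(accepted), , drop = FALSE]
  })
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  origin_set(res[order(res$chrom, res$origin), , drop = FALSE])
}

#' Write an origin set as BED6 plus an audit table
#'
#' Each origin is written as a 1 bp interval; the name column carries the
#' strand masses as `minus:plus`.
#'
#' @param origins An [origin_set()].
#' @param path BED output path.
#' @param audit_path Optional path for a tab-delimited table with all
#'   columns.
#' @return `path`, invisibly.
#' @export
write_origins <- function(origins, path, audit_path = NULL) {
  bed <- data.frame(chrom = origins$chrom, start = origins$origin,
                    end = origins$origin + 1L,
                    name = sprintf("%s:%s",
                                   format(origins$minus_mass, trim = TRUE),
                                   format(origins$plus_mass, trim = TRUE)),
                    score = 0, strand = ".")
  write_bed(bed, path)
  if (!is.null(audit_path))
    utils::write.table(as.data.frame(origins), audit_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read origins written by [write_origins()]
#'
#' @param path BED file path.
#' @return An [origin_set()] (masses parsed from the name column when
#'   present).
#' @export
read_origins <- function(path) {
  bed <- read_bed(path)
  masses <- strsplit(bed$motif_id, ":", fixed = TRUE)
  getm <- function(i) vapply(masses, function(x)
    suppressWarnings(as.numeric(x[i])), numeric(1))
  origin_set(data.frame(chrom = bed$chrom, origin = bed$start,
                        minus_mass = getm(1L), plus_mass = getm(2L),
                        stringsAsFactors = FALSE))
}
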