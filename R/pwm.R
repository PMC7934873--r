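# Position weight matrix scanning with exact p-value threshold calibration.
#
# A PWM is scored as a log2 likelihood ratio (bits) against an i.i.d.
# background model. The score threshold corresponding to a target p-value is
# obtained from the exact null score distribution, computed by dynamic
# programming over scores discretized to a fixed bin width.

# Bin width (bits) used to discretize per-position scores in the null DP.
# The worst-case threshold error is L * PWM_SCORE_BIN / 2, far below the score
# spacing of short motifs.
PWM_SCORE_BIN <- 0.01

#' Construct a position weight matrix
#'
#' @param motif_id Motif identifier.
#' @param probs Numeric `L x 4` matrix of per-position base probabilities in
#'   A, C, G, T column order; each row must sum to 1 (tolerance `1e-9` after
#'   pseudocount normalization).
#' @param background Length-4 background base probabilities (A, C, G, T);
#'   must sum to 1. Default uniform.
#' @param pseudocount Nonnegative pseudocount mixed into `probs` as
#'   `(p + pseudocount * background) / (1 + pseudocount)`, eliminating zero
#'   probabilities when positive.
#' @return An object of class `pwm`: a list with elements `motif_id`,
#'   `probs` (pseudocount-adjusted), `background`, `pseudocount`, `length`.
#' @export
pwm <- function(motif_id, probs, background = rep(0.25, 4), pseudocount = 0) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L || nrow(probs) < 1L)
    stopf("motif %s: `probs` must be an L x 4 matrix with L >= 1", motif_id)
  if (any(probs < 0) || any(!is.finite(probs)))
    stopf("motif %s: probabilities must be finite and nonnegative", motif_id)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6)
    stopf("motif %s: `background` must be 4 probabilities summing to 1",
          motif_id)
  if (!is_number(pseudocount) || pseudocount < 0)
    stopf("motif %s: `pseudocount` must be a nonnegative number", motif_id)
  bad <- which(abs(rowSums(probs) - 1) > 1e-4)
  if (length(bad))
    stopf("motif %s: probability row %d sums to %.6g, expected 1",
          motif_id, bad[1L], rowSums(probs)[bad[1L]])
  adj <- sweep(probs, 2L, background * pseudocount, "+") / (1 + pseudocount)
  adj <- adj / rowSums(adj)  # remove residual float drift; rows sum to 1 +- 1e-9
  dimnames(adj) <- list(NULL, DNA_BASES)
  structure(list(motif_id = as.character(motif_id), probs = adj,
                 background = as.numeric(background),
                 pseudocount = pseudocount, length = nrow(adj)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (length %d, pseudocount %g)\n",
              x$motif_id, x$length, x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

#' Build a PWM concentrated on a consensus sequence
#'
#' Useful for simulations: the consensus base receives probability
#' `certainty` at each position and the remainder is split evenly.
#'
#' @param consensus DNA string over ACGT.
#' @param certainty Probability of the consensus base per position.
#' @param motif_id Identifier (defaults to the consensus itself).
#' @inheritParams pwm
#' @return A [pwm()] object.
#' @export
pwm_from_consensus <- function(consensus, certainty = 0.97,
                               motif_id = consensus,
                               background = rep(0.25, 4), pseudocount = 0) {
  codes <- encode_dna(consensus)
  if (anyNA(codes)) stopf("`consensus` must contain only A/C/G/T")
  L <- length(codes)
  probs <- matrix((1 - certainty) / 3, nrow = L, ncol = 4L)
  probs[cbind(seq_len(L), codes)] <- certainty
  pwm(motif_id, probs, background = background, pseudocount = pseudocount)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#' The alphabet must be DNA (ACGT). If the file carries a
#' `Background letter frequencies` section it is attached to every motif,
#' otherwise the background is uniform.
#'
#' @param path Path to a MEME minimal-format motif file.
#' @param pseudocount Pseudocount applied to every motif (see [pwm()]).
#' @return List of [pwm()] objects, in file order.
#' @export
read_meme <- function(path, pseudocount = 0) {
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)

  alpha_ln <- grep("^ALPHABET", trimmed)
  if (length(alpha_ln)) {
    alpha <- gsub("[^A-Za-z]", "", sub("^ALPHABET=?", "", trimmed[alpha_ln[1L]]))
    if (toupper(alpha) != "ACGT")
      stopf("%s line %d: alphabet must be ACGT, got '%s'",
            path, alpha_ln[1L], alpha)
  }

  background <- rep(0.25, 4)
  bg_ln <- grep("^Background letter frequencies", trimmed)
  if (length(bg_ln)) {
    # frequencies may span several following lines: "A 0.25 C 0.25 ..."
    toks <- character()
    i <- bg_ln[1L] + 1L
    while (i <= length(trimmed) && grepl("^[ACGTacgt]\\s", trimmed[i])) {
      toks <- c(toks, strsplit(trimmed[i], "\\s+")[[1L]])
      i <- i + 1L
    }
    if (length(toks) >= 8L) {
      freq <- as.numeric(toks[seq(2L, length(toks), by = 2L)])
      names(freq) <- toupper(toks[seq(1L, length(toks), by = 2L)])
      if (!all(DNA_BASES %in% names(freq)) || anyNA(freq))
        stopf("%s line %d: malformed background frequencies", path, bg_ln[1L])
      background <- as.numeric(freq[DNA_BASES])
    }
  }

  motif_lns <- grep("^MOTIF\\b", trimmed)
  if (!length(motif_lns)) stopf("%s: no MOTIF blocks found", path)

  motifs <- vector("list", length(motif_lns))
  for (m in seq_along(motif_lns)) {
    ln <- motif_lns[m]
    id <- strsplit(trimmed[ln], "\\s+")[[1L]][2L]
    if (is.na(id)) stopf("%s line %d: MOTIF line has no identifier", path, ln)
    block_end <- if (m < length(motif_lns)) motif_lns[m + 1L] - 1L
                 else length(trimmed)
    hdr <- grep("^letter-probability matrix", trimmed[ln:block_end]) + ln - 1L
    if (!length(hdr))
      stopf("%s motif %s (line %d): missing letter-probability matrix", path, id, ln)
    hdr <- hdr[1L]
    w <- suppressWarnings(
      as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", trimmed[hdr])))
    rows <- list(); i <- hdr + 1L
    while (i <= block_end && length(rows) < (w %||% Inf)) {
      if (!nzchar(trimmed[i])) { i <- i + 1L; next }
      vals <- suppressWarnings(as.numeric(strsplit(trimmed[i], "\\s+")[[1L]]))
      if (anyNA(vals) || length(vals) != 4L) {
        if (is.na(w)) break
        stopf("%s motif %s line %d: expected 4 numeric probabilities", path, id, i)
      }
      if (abs(sum(vals) - 1) > 5e-3)
        stopf("%s motif %s line %d: probability row sums to %.4g, expected 1",
              path, id, i, sum(vals))
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (!length(rows) || (!is.na(w) && length(rows) != w))
      stopf("%s motif %s (line %d): expected %s probability rows, found %d",
            path, id, hdr, w %||% ">=1", length(rows))
    motifs[[m]] <- pwm(id, do.call(rbind, rows), background = background,
                       pseudocount = pseudocount)
  }
  motifs
}

#' Log-odds score table for a PWM
#'
#' `score[i, b] = log2(probs[i, b] / background[b])` in bits, using the
#' pseudocount-adjusted probabilities stored in the PWM. Zero probabilities
#' (possible only at pseudocount 0) yield `-Inf`.
#'
#' @param x A [pwm()] object.
#' @return An object of class `pwm_scores`: list with `motif_id`,
#'   `scores` (`L x 4` matrix, bits), `background`.
#' @export
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  if (any(x$background <= 0))
    stopf("motif %s: background entries must be positive for log-odds scoring",
          x$motif_id)
  scores <- log2(sweep(x$probs, 2L, x$background, "/"))
  structure(list(motif_id = x$motif_id, scores = scores,
                 background = x$background),
            class = "pwm_scores")
}

# Discretized null score distribution of a score table under the i.i.d.
# background. Returns bin probabilities and the bit value of the first bin.
# Mass on windows containing a -Inf position is excluded (such windows can
# never exceed a finite threshold).
.null_score_distribution <- function(score_table, background,
                                     bin_width = PWM_SCORE_BIN) {
  scores <- score_table$scores
  L <- nrow(scores)
  k <- round(scores / bin_width)         # integer bins; -Inf propagates
  dist <- 1                              # P over offset bins, base = 0
  base <- 0L
  for (i in seq_len(L)) {
    finite <- is.finite(k[i, ])
    ki <- k[i, finite]
    bg <- background[finite]
    kmin <- min(ki)
    width <- max(ki) - kmin
    new <- numeric(length(dist) + width)
    for (j in seq_along(ki)) {
      off <- ki[j] - kmin
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * bg[j]
    }
    dist <- new
    base <- base + kmin
  }
  list(prob = dist, base = base, bin_width = bin_width)
}

#' Score threshold attaining a target p-value
#'
#' Computes the exact null distribution of window scores under the i.i.d.
#' background model by dynamic programming over scores discretized to
#' `bin_width` bits (default 0.01), then returns the smallest score `s` with
#' `P(score >= s | background) <= pvalue`. The discretization limits the
#' threshold resolution to `L * bin_width` in the worst case.
#'
#' If `pvalue` is below the smallest attainable exceedance probability
#' (`1/4^L` under a uniform background), the maximum attainable score is
#' returned with a warning.
#'
#' @param score_table A `pwm_scores` object from [log_odds()].
#' @param background Background probabilities; defaults to those stored in
#'   `score_table`.
#' @param pvalue Target p-value in (0, 1).
#' @param bin_width Discretization bin width in bits.
#' @return Score threshold in bits.
#' @export
threshold_from_pvalue <- function(score_table, background = NULL, pvalue,
                                  bin_width = PWM_SCORE_BIN) {
  stopifnot(inherits(score_table, "pwm_scores"))
  background <- background %||% score_table$background
  if (!is_number(pvalue) || pvalue <= 0 || pvalue > 1)
    stopf("`pvalue` must be in (0, 1]")
  nd <- .null_score_distribution(score_table, background, bin_width)
  tail <- rev(cumsum(rev(nd$prob)))
  hit <- which(tail <= pvalue)
  if (!length(hit)) {
    warnf("motif %s: pvalue %.3g below minimum attainable exceedance %.3g; returning maximum score",
          score_table$motif_id, pvalue, tail[length(tail)])
    return((nd$base + length(nd$prob) - 1L) * bin_width)
  }
  (nd$base + hit[1L] - 1L) * bin_width
}

# Score every window of `codes` (integer-encoded sequence) with an L x 4 table.
# Windows containing NA codes score NA.
.window_scores <- function(codes, scores) {
  L <- nrow(scores)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  total <- numeric(n)
  for (i in seq_len(L)) {
    row <- scores[i, ]
    total <- total + row[codes[i:(i + n - 1L)]]
  }
  total
}

#' Scan sequences for motif matches above a threshold
#'
#' Every window on the forward strand and on the reverse complement scoring
#' at least `threshold` is reported. Windows containing `N` are skipped.
#' Reverse-strand hits are reported in forward coordinates (start of the
#' matched span). Overlapping hits are all reported.
#'
#' @param sequences Named character vector of DNA sequences (names are
#'   chromosome identifiers), or a single unnamed sequence (named `seq1`).
#' @param score_table A `pwm_scores` object from [log_odds()].
#' @param threshold Minimum score in bits, e.g. from
#'   [threshold_from_pvalue()].
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `score` (bits), `motif_id`; zero rows if nothing
#'   matches.
#' @export
scan_sequences <- function(sequences, score_table, threshold) {
  stopifnot(inherits(score_table, "pwm_scores"))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  scores <- score_table$scores
  L <- nrow(scores)
  rc_scores <- scores[L:1, 4:1, drop = FALSE]   # reverse complement table
  dimnames(rc_scores) <- dimnames(scores)
  out <- vector("list", 2L * length(sequences))
  k <- 0L
  for (chrom in names(sequences)) {
    codes <- encode_dna(sequences[[chrom]])
    for (strand in c("+", "-")) {
      tab <- if (strand == "+") scores else rc_scores
      sc <- .window_scores(codes, tab)
      keep <- which(!is.na(sc) & sc >= threshold)
      if (length(keep)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          chrom = chrom, start = keep - 1L, end = keep - 1L + L,
          strand = strand, score = sc[keep],
          motif_id = score_table$motif_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), motif_id = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}
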