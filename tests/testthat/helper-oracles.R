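# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorized code paths: per-window loops, full 4^L
# enumeration, and explicit complementation.

# Score one window (character vector of bases) against an L x 4 bit-score
# matrix; NA if any base is not ACGT.
oracle_score_window <- function(bases, scores) {
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  total <- 0
  for (i in seq_along(idx)) total <- total + scores[i, idx[i]]
  total
}

# Exhaustive per-window scan of one sequence on both strands.
oracle_scan <- function(seq, scores, threshold) {
  L <- nrow(scores)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  n <- length(chars) - L + 1L
  if (n < 1L) return(data.frame(start = integer(), strand = character(),
                                score = numeric()))
  for (s in seq_len(n)) {
    win <- chars[s:(s + L - 1L)]
    fw <- oracle_score_window(win, scores)
    if (!is.na(fw) && fw >= threshold)
      hits[[length(hits) + 1L]] <- data.frame(start = s - 1L, strand = "+",
                                              score = fw)
    rc <- rev(unname(comp[win]))
    bw <- if (anyNA(rc)) NA_real_ else oracle_score_window(rc, scores)
    if (!is.na(bw) && bw >= threshold)
      hits[[length(hits) + 1L]] <- data.frame(start = s - 1L, strand = "-",
                                              score = bw)
  }
  if (!length(hits)) return(data.frame(start = integer(),
                                       strand = character(),
                                       score = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Exact null score distribution by enumerating all 4^L words.
# Returns the smallest achievable score s with P(score >= s) <= pvalue,
# or the maximum achievable score if pvalue is below the attainable minimum.
oracle_threshold <- function(scores, background, pvalue) {
  L <- nrow(scores)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(words))
  pr <- numeric(nrow(words))
  for (w in seq_len(nrow(words))) {
    s <- 0; p <- 1
    for (i in seq_len(L)) {
      s <- s + scores[i, words[w, i]]
      p <- p * background[words[w, i]]
    }
    sc[w] <- s; pr[w] <- p
  }
  finite <- is.finite(sc)
  sc <- sc[finite]; pr <- pr[finite]
  us <- sort(unique(sc), decreasing = TRUE)
  tails <- cumsum(vapply(us, function(v) sum(pr[sc == v]), numeric(1)))
  ok <- which(tails <= pvalue + 1e-12)
  if (!length(ok)) return(us[1L])
  us[max(ok)]   # smallest score among those with tail <= pvalue
}

# All finite scores achievable by some word, by enumeration.
oracle_achievable_scores <- function(scores) {
  L <- nrow(scores)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(words))
  for (w in seq_len(nrow(words))) {
    s <- 0
    for (i in seq_len(L)) s <- s + scores[i, words[w, i]]
    sc[w] <- s
  }
  sort(unique(sc[is.finite(sc)]))
}

# Exact exceedance probability P(score >= t) by enumeration.
oracle_exceedance <- function(scores, background, t) {
  L <- nrow(scores)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  total <- 0
  for (w in seq_len(nrow(words))) {
    s <- 0; p <- 1
    for (i in seq_len(L)) {
      s <- s + scores[i, words[w, i]]
      p <- p * background[words[w, i]]
    }
    if (is.finite(s) && s >= t) total <- total + p
  }
  total
}

# Random PWM of length L (Dirichlet rows), with pseudocount so all scores
# are finite.
random_pwm <- function(L, motif_id = "rnd", concentration = 0.8) {
  probs <- t(vapply(seq_len(L), function(i) {
    x <- stats::rgamma(4, concentration)
    x / sum(x)
  }, numeric(4)))
  pwm(motif_id, probs, pseudocount = 0.05)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Minimal MEME-format fixture writer.
write_meme_fixture <- function(path, motifs, background = NULL) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  if (!is.null(background))
    lines <- c(lines, "Background letter frequencies",
               sprintf("A %g C %g G %g T %g", background[1], background[2],
                       background[3], background[4]), "")
  for (id in names(motifs)) {
    m <- motifs[[id]]
    lines <- c(lines, sprintf("MOTIF %s", id),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m)),
               apply(m, 1L, function(r) paste(sprintf("%.6f", r),
                                              collapse = " ")),
               "")
  }
  writeLines(lines, path)
  path
}

# Build a strand_coverage object from sparse (position, count) spikes.
coverage_from_spikes <- function(len, minus = NULL, plus = NULL,
                                 chrom = "chr1") {
  p <- integer(len); m <- integer(len)
  if (!is.null(plus)) p[plus[, 1] + 1L] <- plus[, 2]
  if (!is.null(minus)) m[minus[, 1] + 1L] <- minus[, 2]
  strand_coverage(plus = stats::setNames(list(p), chrom),
                  minus = stats::setNames(list(m), chrom),
                  chrom_sizes = stats::setNames(len, chrom))
}
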