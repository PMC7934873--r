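# Motif displacement (MD) scoring.
#
# For one motif, the MD score is the proportion of its genomic instances
# whose midpoint lies within a small radius r (default 150 bp) of the
# nearest eRNA origin, among those within a large radius R (default
# 1500 bp) — i.e. colocalization of the motif with enhancer RNA origins
# measured inside a 2R (3000 bp) window. Differences between two
# conditions are tested with a two-proportion z-test.

#' Signed distances from motif instances to their nearest eRNA origin
#'
#' Each instance contributes at most once: its midpoint
#' `floor((start + end) / 2)` is assigned to the nearest origin on the same
#' chromosome (ties between two equidistant origins resolve toward the
#' smaller origin coordinate), and the signed distance is
#' `midpoint - origin`. Instances farther than `R` from every origin are
#' dropped.
#'
#' @param instances Data frame of motif hits with columns `chrom`, `start`,
#'   `end`, `motif_id` (e.g. from [scan_sequences()] or a motif BED).
#' @param origins An [origin_set()] or data frame with `chrom`, `origin`.
#' @param R Large radius in bases (window halfwidth).
#' @return Data frame with columns `motif_id`, `chrom`, `midpoint`,
#'   `origin`, `distance`.
#' @export
motif_distances <- function(instances, origins, R = 1500) {
  stopifnot(all(c("chrom", "start", "end") %in% names(instances)),
            all(c("chrom", "origin") %in% names(origins)))
  if (!is_number(R) || R <= 0) stopf("`R` must be positive")
  if (is.null(instances$motif_id)) instances$motif_id <- "motif"
  if (nrow(instances) == 0L || nrow(origins) == 0L)
    return(data.frame(motif_id = character(), chrom = character(),
                      midpoint = integer(), origin = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  unknown <- setdiff(unique(instances$chrom), unique(origins$chrom))
  # instances on chromosomes without origins simply have no origin within R;
  # an entirely disjoint chromosome set is an input error
  if (length(unknown) == length(unique(instances$chrom)) &&
      length(unknown) > 0L)
    stopf("no shared chromosomes between instances (%s) and origins (%s)",
          paste(unique(instances$chrom), collapse = ","),
          paste(unique(origins$chrom), collapse = ","))

  mids <- as.integer(floor((instances$start + instances$end) / 2))
  out <- vector("list", length(unique(instances$chrom)))
  names(out) <- unique(instances$chrom)
  for (chrom in names(out)) {
    idx <- which(instances$chrom == chrom)
    ori <- sort(unique(origins$origin[origins$chrom == chrom]))
    if (!length(ori)) next
    m <- mids[idx]
    # nearest origin; tie (equidistant) -> smaller origin coordinate
    right <- findInterval(m, ori) + 1L          # first origin >= m (index)
    left <- right - 1L
    left_ok <- left >= 1L
    right_ok <- right <= length(ori)
    d_left <- ifelse(left_ok, m - ori[pmax(left, 1L)], Inf)
    d_right <- ifelse(right_ok, ori[pmin(right, length(ori))] - m, Inf)
    use_left <- d_left <= d_right                # tie -> left (smaller coord)
    nearest <- ifelse(use_left, ori[pmax(left, 1L)],
                      ori[pmin(right, length(ori))])
    dist <- m - nearest
    keep <- abs(dist) <= R
    if (any(keep))
      out[[chrom]] <- data.frame(
        motif_id = instances$motif_id[idx][keep], chrom = chrom,
        midpoint = m[keep], origin = as.integer(nearest[keep]),
        distance = as.integer(dist[keep]), stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(motif_id = character(), chrom = character(),
                      midpoint = integer(), origin = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compute MD scores from signed distances
#'
#' `h` counts distances with `|d| <= r`, `H` counts `|d| <= R`, and
#' `md = h / H`. Radii are inclusive. Motifs with `H = 0` are flagged
#' undefined (`md = NA`) and must be excluded from differential testing.
#'
#' @param distances Output of [motif_distances()], or a bare numeric vector
#'   of signed distances (treated as one motif).
#' @param r Small radius (bases), default 150.
#' @param R Large radius (bases), default 1500.
#' @return Data frame with columns `motif_id`, `h`, `H`, `md`, `r`, `R`.
#' @export
compute_md <- function(distances, r = 150, R = 1500) {
  if (r >= R) stopf("`r` (%g) must be smaller than `R` (%g)", r, R)
  single <- is.numeric(distances)
  if (single)
    distances <- data.frame(motif_id = rep("motif", length(distances)),
                            distance = distances)
  stopifnot(all(c("motif_id", "distance") %in% names(distances)))
  ids <- unique(distances$motif_id)
  # a bare numeric vector is one motif even when it has no distances left
  if (single && !length(ids)) ids <- "motif"
  res <- do.call(rbind, lapply(ids, function(id) {
    d <- distances$distance[distances$motif_id == id &
                              abs(distances$distance) <= R]
    H <- length(d)
    h <- sum(abs(d) <= r)
    data.frame(motif_id = id, h = h, H = H,
               md = if (H > 0) h / H else NA_real_,
               r = r, R = R, stringsAsFactors = FALSE)
  }))
  res %||% data.frame(motif_id = character(), h = integer(), H = integer(),
                      md = numeric(), r = numeric(), R = numeric(),
                      stringsAsFactors = FALSE)
}

#' Two-proportion z-test between MD scores of two conditions
#'
#' With pooled proportion `phat = (h_a + h_b) / (H_a + H_b)`,
#' `z = (md_a - md_b) / sqrt(phat (1 - phat) (1/H_a + 1/H_b))` and the
#' p-value is the two-sided standard-normal tail. A motif is significant
#' when `p <= alpha` (default `1e-4`, the conventional MD significance
#' threshold). Degenerate pooled proportions (0 or 1) yield `z = NA`,
#' `p = 1`, not significant, with `degenerate = TRUE`.
#'
#' Motifs with undefined MD (`H = 0`) in either condition are dropped with
#' a warning; no test statistic exists for them.
#'
#' @param a,b MD tables from [compute_md()] for the two conditions.
#' @param alpha Significance threshold on the two-sided p-value.
#' @return Data frame with columns `motif_id`, `md_a`, `md_b`, `h_a`,
#'   `H_a`, `h_b`, `H_b`, `z`, `p`, `significant`, `degenerate`.
#' @export
diff_md <- function(a, b, alpha = 1e-4) {
  stopifnot(all(c("motif_id", "h", "H", "md") %in% names(a)),
            all(c("motif_id", "h", "H", "md") %in% names(b)))
  if (!is_number(alpha) || alpha <= 0 || alpha > 1)
    stopf("`alpha` must be in (0, 1]")
  merged <- merge(a[c("motif_id", "h", "H", "md")],
                  b[c("motif_id", "h", "H", "md")],
                  by = "motif_id", suffixes = c("_a", "_b"))
  undef <- merged$H_a == 0 | merged$H_b == 0
  if (any(undef)) {
    warnf("dropping %d motif(s) with undefined MD (H = 0) from testing",
          sum(undef))
    merged <- merged[!undef, , drop = FALSE]
  }
  phat <- (merged$h_a + merged$h_b) / (merged$H_a + merged$H_b)
  se <- sqrt(phat * (1 - phat) * (1 / merged$H_a + 1 / merged$H_b))
  degenerate <- phat %in% c(0, 1)
  z <- ifelse(degenerate, NA_real_, (merged$md_a - merged$md_b) / se)
  p <- ifelse(degenerate, 1, 2 * stats::pnorm(-abs(z)))
  data.frame(motif_id = merged$motif_id,
             md_a = merged$md_a, md_b = merged$md_b,
             h_a = merged$h_a, H_a = merged$H_a,
             h_b = merged$h_b, H_b = merged$H_b,
             z = z, p = p,
             significant = !degenerate & p <= alpha,
             degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Barcode matrix of motif-to-origin distances
#'
#' Histogram of signed distances over `[-R, R]` with `n_bins` equal-width
#' bins per motif, the binned analogue of a barcode heat strip. Bins are
#' half-open `[lo, hi)` with the last bin closed, so with `n_bins` even the
#' value 0 sits on a bin edge and falls in the right-central bin.
#'
#' @param distances Output of [motif_distances()], or a numeric vector.
#' @param R Window halfwidth (bases).
#' @param n_bins Number of bins; must be even.
#' @return Numeric matrix (motifs x bins) of class `barcode_matrix`, with
#'   attribute `bin_edges` (length `n_bins + 1`).
#' @export
barcode_matrix <- function(distances, R = 1500, n_bins = 100) {
  if (!is_count(n_bins) || n_bins < 2 || n_bins %% 2 != 0)
    stopf("`n_bins` must be a positive even integer (keeps 0 on a bin edge)")
  if (is.numeric(distances))
    distances <- data.frame(motif_id = rep("motif", length(distances)),
                            distance = distances)
  edges <- seq(-R, R, length.out = n_bins + 1)
  ids <- unique(distances$motif_id)
  mat <- matrix(0L, nrow = length(ids), ncol = n_bins,
                dimnames = list(ids, NULL))
  for (id in ids) {
    d <- distances$distance[distances$motif_id == id]
    d <- d[abs(d) <= R]
    bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), n_bins)
    mat[id, ] <- tabulate(bin, nbins = n_bins)
  }
  structure(mat, bin_edges = edges, class = c("barcode_matrix", "matrix"))
}

#' Plot a barcode matrix as heat strips
#'
#' Row-normalized heat strips of motif-to-origin distance frequencies;
#' darker is more frequent.
#'
#' @param x A [barcode_matrix()].
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot_barcode <- function(x, ...) {
  stopifnot(inherits(x, "barcode_matrix"))
  edges <- attr(x, "bin_edges")
  norm <- x / pmax(rowSums(x), 1L)
  graphics::image(x = edges, y = seq_len(nrow(x)),
                  z = t(norm[rev(seq_len(nrow(x))), , drop = FALSE]),
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = "distance to eRNA origin (bp)", ylab = "",
                  yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(x)), labels = rev(rownames(x)),
                 las = 2, cex.axis = 0.7)
  invisible(x)
}
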