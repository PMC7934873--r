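# Pseudo-bulk per-nucleus contrasts of chromatin accessibility and gene
# expression across disease groups or genotypes.
#
# Accessibility: the response is the indicator of any fragment in the
# region, modeled by logistic regression with a log-depth covariate;
# the headline fold change is the ratio of depth-normalized group mean
# counts (a probability-model coefficient is not a count ratio).
# Expression: negative binomial regression with a log(depth) offset; the
# fold change is exp of the group coefficient. Both p-values come from
# likelihood-ratio tests of the group term; Bonferroni adjustment is
# applied across however many tests a run performs.

.required_nucleus_cols <- c("nucleus_id", "sample_id", "disease", "genotype",
                            "cell_type", "total_counts")

.check_nucleus_table <- function(table) {
  missing <- setdiff(.required_nucleus_cols, names(table))
  if (length(missing))
    stopf("nucleus table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(table$total_counts < 0))
    stopf("`total_counts` must be nonnegative")
  invisible(table)
}

#' Read / write a per-nucleus feature-count table
#'
#' Tab-delimited with a header; required columns `nucleus_id`, `sample_id`,
#' `disease`, `genotype`, `cell_type`, `total_counts`, plus one column per
#' feature.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_nucleus_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  .check_nucleus_table(tab)
}

#' @rdname read_nucleus_table
#' @param table Nucleus table to write.
#' @export
write_nucleus_table <- function(table, path) {
  .check_nucleus_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subset nuclei by cell type, disease and genotype
#'
#' @param table Nucleus table (see [read_nucleus_table()]).
#' @param cell_types Character vector of cell-type labels to keep.
#' @param disease,genotype Optional label filters.
#' @return The subset, with a `flagged_empty` attribute when no nucleus
#'   matches.
#' @export
select_nuclei <- function(table, cell_types = NULL, disease = NULL,
                          genotype = NULL) {
  .check_nucleus_table(table)
  check_labels <- function(requested, column, name) {
    avail <- unique(table[[column]])
    bad <- setdiff(requested, avail)
    if (length(bad))
      stopf("unknown %s label(s) %s; available: %s", name,
            paste(bad, collapse = ", "), paste(avail, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(table))
  if (!is.null(cell_types)) {
    check_labels(cell_types, "cell_type", "cell type")
    keep <- keep & table$cell_type %in% cell_types
  }
  if (!is.null(disease)) {
    check_labels(disease, "disease", "disease")
    keep <- keep & table$disease %in% disease
  }
  if (!is.null(genotype)) {
    check_labels(genotype, "genotype", "genotype")
    keep <- keep & table$genotype %in% genotype
  }
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warnf("selection matched no nuclei")
    attr(out, "flagged_empty") <- TRUE
  }
  out
}

# Shared preparation for the two regression contrasts.
.two_groups <- function(subset, group_variable) {
  if (!group_variable %in% c("disease", "genotype"))
    stopf("`group_variable` must be 'disease' or 'genotype'")
  levels_ <- unique(subset[[group_variable]])
  if (length(levels_) != 2L)
    stopf("`%s` must have exactly two levels in the subset, found: %s",
          group_variable, paste(levels_, collapse = ", "))
  # reference ordering: control before IPF, GG (WT) before TT (variant);
  # other labels use byte order so results do not depend on the locale
  canonical <- list(c("control", "IPF"), c("GG", "TT"))
  hit <- Filter(function(x) setequal(x, levels_), canonical)
  levels_ <- if (length(hit)) hit[[1L]] else sort(levels_, method = "radix")
  g <- as.integer(subset[[group_variable]] == levels_[2L])
  if (min(table(g)) == 0L) stopf("both groups must be nonempty")
  list(g = g, levels = levels_)
}

# Depth-normalized group mean counts per 1e4 total counts. The pseudo-offset
# of 1 count per 1e4 total is applied only when a group mean is zero, to keep
# the ratio finite; such results carry degenerate = TRUE.
.mean_ratio <- function(counts, depth, g) {
  norm <- counts / depth * 1e4
  m0 <- mean(norm[g == 0L]); m1 <- mean(norm[g == 1L])
  degenerate <- (m0 == 0 || m1 == 0)
  if (degenerate) { m0 <- m0 + 1; m1 <- m1 + 1 }
  list(fc = m1 / m0, degenerate = degenerate)
}

.regression_result <- function(feature, contrast, fold_change, coef_fc, p,
                               n_a, n_b, degenerate = FALSE,
                               fallback = NA_character_) {
  structure(data.frame(feature = feature, contrast = contrast,
                       fold_change = fold_change,
                       coef_fold_change = coef_fc, p = p,
                       p_adj = NA_real_, n_a = n_a, n_b = n_b,
                       degenerate = degenerate, fallback = fallback,
                       stringsAsFactors = FALSE),
            class = c("regression_result", "data.frame"))
}

#' Differential accessibility by logistic regression
#'
#' Fits `indicator(count > 0) ~ group + log(total_counts)` (binomial logit)
#' and tests the group term by likelihood ratio. The headline
#' `fold_change` is the ratio of depth-normalized mean feature counts
#' (second group level over first); `coef_fold_change` is `exp` of the
#' logistic group coefficient (an odds ratio), reported for comparison.
#'
#' Complete separation is flagged and the p-value falls back to a
#' two-sided Fisher exact test on the 2x2 accessibility table
#' (`fallback = "fisher"`).
#'
#' @param subset Nucleus table subset (see [select_nuclei()]).
#' @param feature Feature column name (e.g. `"enhancer_fragments"`).
#' @param group_variable `"disease"` or `"genotype"`.
#' @return A one-row `regression_result` data frame.
#' @export
diff_accessibility <- function(subset, feature,
                               group_variable = "disease") {
  .check_nucleus_table(subset)
  if (!feature %in% names(subset))
    stopf("feature '%s' not found in the nucleus table", feature)
  grp <- .two_groups(subset, group_variable)
  g <- grp$g
  y <- as.integer(subset[[feature]] > 0)
  ld <- log(pmax(subset$total_counts, 1))

  fit <- suppressWarnings(
    stats::glm(y ~ g + ld, family = stats::binomial()))
  fit0 <- suppressWarnings(stats::glm(y ~ ld, family = stats::binomial()))
  lrt <- stats::anova(fit0, fit, test = "LRT")
  p <- lrt$`Pr(>Chi)`[2L]
  separated <- !fit$converged || any(abs(stats::coef(fit)) > 15) ||
    min(table(y, g)) == 0L
  fallback <- NA_character_
  if (separated) {
    p <- stats::fisher.test(table(factor(y, levels = 0:1),
                                  factor(g, levels = 0:1)))$p.value
    fallback <- "fisher"
  }
  mr <- .mean_ratio(as.numeric(subset[[feature]]), subset$total_counts, g)
  .regression_result(
    feature = feature,
    contrast = sprintf("%s: %s vs %s", group_variable,
                       grp$levels[2L], grp$levels[1L]),
    fold_change = mr$fc,
    coef_fc = unname(exp(stats::coef(fit)["g"])),
    p = p, n_a = sum(g == 0L), n_b = sum(g == 1L),
    degenerate = mr$degenerate || separated, fallback = fallback)
}

#' Differential expression by negative binomial regression
#'
#' Fits `count ~ group + offset(log(total_counts))` with a negative
#' binomial likelihood (dispersion estimated by maximum likelihood) and
#' tests the group term by likelihood ratio. `fold_change` is `exp` of the
#' group coefficient; the depth offset makes it depth-invariant.
#' Nonconvergence falls back to a Poisson GLM (`fallback = "poisson"`).
#'
#' @inheritParams diff_accessibility
#' @param gene Feature column holding the gene's per-nucleus counts.
#' @return A one-row `regression_result` data frame.
#' @export
diff_expression <- function(subset, gene, group_variable = "disease") {
  .check_nucleus_table(subset)
  if (!gene %in% names(subset))
    stopf("gene column '%s' not found in the nucleus table", gene)
  grp <- .two_groups(subset, group_variable)
  g <- grp$g
  y <- as.numeric(subset[[gene]])
  off <- log(pmax(subset$total_counts, 1))

  fallback <- NA_character_
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ g + offset(off))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) {
    fit0 <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ 1 + offset(off))),
      error = function(e) NULL)
    if (!is.null(fit0)) {
      stat <- 2 * (stats::logLik(fit)[1L] - stats::logLik(fit0)[1L])
      p <- stats::pchisq(pmax(stat, 0), df = 1L, lower.tail = FALSE)
    } else fit <- NULL
  }
  if (is.null(fit) || !fit$converged) {
    fit <- suppressWarnings(
      stats::glm(y ~ g + offset(off), family = stats::poisson()))
    fit0 <- suppressWarnings(
      stats::glm(y ~ 1 + offset(off), family = stats::poisson()))
    p <- stats::anova(fit0, fit, test = "LRT")$`Pr(>Chi)`[2L]
    fallback <- "poisson"
  }
  .regression_result(
    feature = gene,
    contrast = sprintf("%s: %s vs %s", group_variable,
                       grp$levels[2L], grp$levels[1L]),
    fold_change = unname(exp(stats::coef(fit)["g"])),
    coef_fc = unname(exp(stats::coef(fit)["g"])),
    p = p, n_a = sum(g == 0L), n_b = sum(g == 1L),
    degenerate = FALSE, fallback = fallback)
}

#' Bonferroni adjustment across a set of contrasts
#'
#' `p_adj = min(1, p * n_tests)`, preserving row order. `n_tests` defaults
#' to the number of results but may be larger when the run tested more
#' contrasts than are tabulated here.
#'
#' @param results One or more `regression_result` rows (rbind-able data
#'   frame with a `p` column).
#' @param n_tests Total number of tests performed.
#' @return `results` with `p_adj` filled in.
#' @export
adjust_bonferroni <- function(results, n_tests = nrow(results)) {
  stopifnot("p" %in% names(results))
  if (!is_count(n_tests) || n_tests < nrow(results))
    stopf("`n_tests` (%s) must be at least the number of results (%d)",
          format(n_tests), nrow(results))
  results$p_adj <- pmin(1, results$p * n_tests)
  results
}

#' Pseudo-bulk coverage profile from per-nucleus fragments
#'
#' Sums per-base fragment overlap across the nuclei in `subset` and
#' normalizes per `1e4` nuclei (so cohorts of different size are
#' comparable).
#'
#' @param subset Nucleus table subset; only its `nucleus_id` values are
#'   used.
#' @param fragments Data frame of fragments with columns `nucleus_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param region List or data frame row with `chrom`, `start`, `end`.
#' @return Data frame with columns `chrom`, `pos` (0-based), `coverage`
#'   (normalized) and attribute `raw` (unnormalized vector); flagged via
#'   attribute `flagged_empty` when the subset is empty.
#' @export
pseudobulk_profile <- function(subset, fragments, region) {
  stopifnot(all(c("nucleus_id", "chrom", "start", "end") %in% names(fragments)),
            all(c("chrom", "start", "end") %in% names(region)))
  if (region$start < 0 || region$end <= region$start)
    stopf("malformed region [%s, %s)", region$start, region$end)
  n_nuc <- nrow(subset)
  width <- region$end - region$start
  raw <- numeric(width)
  # each subset row contributes its nucleus' fragments once, so a duplicated
  # nucleus doubles raw coverage and the per-1e4-nuclei normalization cancels
  mult <- table(subset$nucleus_id)
  fr <- fragments[fragments$nucleus_id %in% names(mult) &
                    fragments$chrom == region$chrom &
                    fragments$end > region$start &
                    fragments$start < region$end, , drop = FALSE]
  if (nrow(fr)) {
    s <- pmax(fr$start, region$start) - region$start + 1L
    e <- pmin(fr$end, region$end) - region$start
    w <- as.numeric(mult[fr$nucleus_id])
    for (i in seq_len(nrow(fr))) raw[s[i]:e[i]] <- raw[s[i]:e[i]] + w[i]
  }
  out <- data.frame(chrom = region$chrom,
                    pos = seq.int(region$start, region$end - 1L),
                    coverage = if (n_nuc > 0) raw * 1e4 / n_nuc else raw)
  attr(out, "raw") <- raw
  if (n_nuc == 0L) {
    warnf("empty nucleus subset: returning zero coverage")
    attr(out, "flagged_empty") <- TRUE
  }
  out
}
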