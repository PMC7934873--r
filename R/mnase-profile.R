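# Tiled MNase-qPCR relative protection profiling.
#
# Under the standard efficiency-2 qPCR model, the fraction of template
# surviving micrococcal nuclease digestion at amplicon i is
# 2^-(Ct_digested_i - Ct_undigested_i). Protection is expressed relative
# to a reference amplicon via the delta-delta-Ct:
#   protection_i = 2^-(dCt_i - dCt_ref),  dCt = Ct_digested - Ct_undigested.
# Values above 1 indicate more nucleosome protection than the reference;
# an additive shift common to all Ct values cancels.

#' Relative protection from a tiled MNase-qPCR Ct table
#'
#' Computed per replicate and summarized as mean and SD across replicates,
#' ordered by amplicon midpoint. Protection at the reference amplicon is
#' exactly 1 in every replicate.
#'
#' @param table Data frame with columns `amplicon_id`, `midpoint`,
#'   `replicate`, `Ct_digested`, `Ct_undigested`
#'   (see [simulate_mnase_ct()]).
#' @param reference_amplicon_id Amplicon used as the delta-delta-Ct
#'   reference; must be present in every replicate.
#' @return Data frame with columns `amplicon_id`, `midpoint`,
#'   `protection_mean`, `protection_sd`, `n_replicates`, `incomplete`
#'   (TRUE when an amplicon is missing from some replicate), ordered by
#'   midpoint. Per-replicate values are attached as attribute
#'   `"replicates"`.
#' @export
relative_protection <- function(table, reference_amplicon_id) {
  need <- c("amplicon_id", "midpoint", "replicate", "Ct_digested",
            "Ct_undigested")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stopf("Ct table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(table$Ct_digested <= 0 | table$Ct_digested >= 45) ||
      any(table$Ct_undigested <= 0 | table$Ct_undigested >= 45))
    stopf("Ct values must lie in (0, 45)")
  reps <- sort(unique(table$replicate))
  ref_reps <- unique(table$replicate[table$amplicon_id ==
                                       reference_amplicon_id])
  if (!reference_amplicon_id %in% table$amplicon_id)
    stopf("reference amplicon '%s' not present in the table",
          reference_amplicon_id)
  if (!all(reps %in% ref_reps))
    stopf("reference amplicon '%s' missing from replicate(s): %s",
          reference_amplicon_id,
          paste(setdiff(reps, ref_reps), collapse = ", "))

  table$dct <- table$Ct_digested - table$Ct_undigested
  ref_dct <- stats::setNames(
    table$dct[table$amplicon_id == reference_amplicon_id][
      match(reps, table$replicate[table$amplicon_id ==
                                    reference_amplicon_id])],
    reps)
  table$protection <- 2^(-(table$dct - ref_dct[as.character(table$replicate)]))

  amps <- unique(table[c("amplicon_id", "midpoint")])
  if (any(duplicated(amps$amplicon_id)))
    stopf("amplicon midpoints must be constant per amplicon_id")
  amps <- amps[order(amps$midpoint), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(amps)), function(i) {
    pr <- table$protection[table$amplicon_id == amps$amplicon_id[i]]
    data.frame(amplicon_id = amps$amplicon_id[i],
               midpoint = amps$midpoint[i],
               protection_mean = mean(pr),
               protection_sd = if (length(pr) > 1L) stats::sd(pr) else NA_real_,
               n_replicates = length(pr),
               incomplete = length(pr) < length(reps),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (any(out$incomplete))
    warnf("amplicon(s) missing replicate values (flagged, not dropped): %s",
          paste(out$amplicon_id[out$incomplete], collapse = ", "))
  attr(out, "replicates") <-
    table[order(table$midpoint, table$replicate),
          c("amplicon_id", "midpoint", "replicate", "protection")]
  out
}

#' Plot a relative-protection profile with error bars
#'
#' @param profile Output of [relative_protection()].
#' @param ... Passed to [graphics::plot()].
#' @return `profile`, invisibly.
#' @export
plot_protection <- function(profile, ...) {
  stopifnot(all(c("midpoint", "protection_mean") %in% names(profile)))
  sd <- ifelse(is.na(profile$protection_sd), 0, profile$protection_sd)
  graphics::plot(profile$midpoint, profile$protection_mean, type = "b",
                 pch = 19, xlab = "amplicon midpoint (bp)",
                 ylab = "relative protection",
                 ylim = range(c(profile$protection_mean - sd,
                                profile$protection_mean + sd)), ...)
  has_sd <- sd > 0
  if (any(has_sd))
    graphics::arrows(profile$midpoint[has_sd],
                     (profile$protection_mean - sd)[has_sd],
                     profile$midpoint[has_sd],
                     (profile$protection_mean + sd)[has_sd],
                     angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 2, col = "gray50")
  invisible(profile)
}
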