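# Synthetic-data generators: genome sequence, eRNA origins, planted motif
# instances, divergent strand-specific read pileups, per-nucleus count
# tables, and tiled MNase-qPCR Ct values — each with a recorded ground
# truth so downstream estimates can be checked against known parameters.
#
# Reproducibility: each generator draws from a seed derived from
# `config$seed` plus a fixed per-operation offset, so running the full
# pipeline from one config is deterministic and the operations do not share
# RNG streams.

.op_seed <- function(seed, offset) (as.numeric(seed) + offset) %% 2147483647

#' Simulation configuration for genome, origins, motifs and coverage
#'
#' @param genome_length Genome length in bases.
#' @param gc_fraction Expected G+C fraction in `[0, 1]`.
#' @param n_origins Number of eRNA origins to place.
#' @param origin_min_spacing Minimum pairwise origin distance (bases); must
#'   exceed `2 * placement_radius`.
#' @param n_motif_instances Number of motif instances to place.
#' @param colocalized_fraction Fraction of instances placed near origins.
#' @param placement_radius Co-localized instances fall within this distance
#'   of an origin (bases).
#' @param reads_per_origin Reads simulated per origin (split across strands).
#' @param read_offset_scale Mean of the geometric origin-to-read offset
#'   (bases).
#' @param noise_read_rate Uniform background reads per base per strand.
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, gc_fraction = 0.5,
                       n_origins = 30, origin_min_spacing = 3000,
                       n_motif_instances = 1000, colocalized_fraction = 0.5,
                       placement_radius = 150, reads_per_origin = 200,
                       read_offset_scale = 60, noise_read_rate = 0,
                       seed = 1) {
  if (!is_count(genome_length) || genome_length < 1)
    stopf("`genome_length` must be a positive integer")
  check_proportion(gc_fraction, "gc_fraction")
  check_proportion(colocalized_fraction, "colocalized_fraction")
  for (nm in c("n_origins", "n_motif_instances", "reads_per_origin")) {
    v <- get(nm)
    if (!is_count(v)) stopf("`%s` must be a nonnegative integer", nm)
  }
  if (!is_number(origin_min_spacing) || origin_min_spacing <= 0)
    stopf("`origin_min_spacing` must be positive")
  if (!is_number(placement_radius) || placement_radius < 0)
    stopf("`placement_radius` must be nonnegative")
  if (origin_min_spacing <= 2 * placement_radius)
    stopf("`origin_min_spacing` (%g) must exceed 2 * placement_radius (%g)",
          origin_min_spacing, 2 * placement_radius)
  if (!is_number(read_offset_scale) || read_offset_scale < 1)
    stopf("`read_offset_scale` must be >= 1")
  if (!is_number(noise_read_rate) || noise_read_rate < 0)
    stopf("`noise_read_rate` must be nonnegative")
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, n_origins = as.integer(n_origins),
                 origin_min_spacing = origin_min_spacing,
                 n_motif_instances = as.integer(n_motif_instances),
                 colocalized_fraction = colocalized_fraction,
                 placement_radius = placement_radius,
                 reads_per_origin = as.integer(reads_per_origin),
                 read_offset_scale = read_offset_scale,
                 noise_read_rate = noise_read_rate, seed = seed,
                 chrom = "chrS"),
            class = "sim_config")
}

#' Simulate a random genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`.
#'
#' @param config A [sim_config()].
#' @return Named character vector of length 1 (chromosome `chrS`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gc <- config$gc_fraction
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- with_seed(.op_seed(config$seed, 0), {
    paste(sample(DNA_BASES, config$genome_length, replace = TRUE, prob = p),
          collapse = "")
  })
  stats::setNames(seq, config$chrom)
}

#' Place eRNA origins with a minimum spacing (ground truth)
#'
#' Origins are uniform over admissible configurations with pairwise distance
#' at least `origin_min_spacing`, all within
#' `[placement_radius, genome_length - placement_radius)`.
#'
#' @param config A [sim_config()].
#' @return An `origin_set` data frame (see [origin_set()]); peak metadata
#'   columns are `NA` for truth origins.
#' @export
place_origins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_origins
  lo <- config$placement_radius
  hi <- config$genome_length - config$placement_radius
  if (n * config$origin_min_spacing > config$genome_length)
    stopf("infeasible packing: %d origins with spacing %g exceed genome length %d",
          n, config$origin_min_spacing, config$genome_length)
  slack <- (hi - lo) - (n - 1) * config$origin_min_spacing - 1
  if (n > 0 && slack < 0)
    stopf("infeasible packing: spacing plus boundary margins exceed genome length")
  pos <- with_seed(.op_seed(config$seed, 1), {
    if (n == 0) integer(0) else {
      u <- sort(floor(stats::runif(n, 0, slack + 1)))
      as.integer(lo + u + (seq_len(n) - 1) * config$origin_min_spacing)
    }
  })
  origin_set(data.frame(chrom = rep(config$chrom, n), origin = pos,
                        stringsAsFactors = FALSE))
}

#' Draw motif instance midpoints relative to origins (ground truth)
#'
#' A fraction `colocalized_fraction` of midpoints are placed uniformly
#' within `±placement_radius` of a randomly chosen origin; the remainder
#' are uniform over the genome. This is the placement model underlying
#' [plant_motifs()], exposed separately so distance statistics can be
#' studied at scales where editing a genome sequence is unnecessary.
#'
#' @param origins An `origin_set` (truth origins).
#' @param config A [sim_config()].
#' @param motif_length Length of the motif, used to keep instances in
#'   bounds.
#' @return Data frame with columns `chrom`, `midpoint`, `colocalized`.
#' @export
draw_motif_positions <- function(origins, config, motif_length = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_motif_instances
  n_coloc <- round_half_up(n * config$colocalized_fraction)
  if (n_coloc > 0 && nrow(origins) == 0)
    stopf("cannot co-localize motif instances: no origins supplied")
  half <- motif_length %/% 2
  lo <- half
  hi <- config$genome_length - (motif_length - half) - 1
  with_seed(.op_seed(config$seed, 2), {
    coloc <- logical(n)
    coloc[seq_len(n_coloc)] <- TRUE
    mid <- integer(n)
    if (n_coloc > 0) {
      anchor <- origins$origin[sample.int(nrow(origins), n_coloc, replace = TRUE)]
      off <- floor(stats::runif(n_coloc, -config$placement_radius,
                                config$placement_radius + 1))
      mid[coloc] <- anchor + off
    }
    n_bg <- n - n_coloc
    if (n_bg > 0)
      mid[!coloc] <- floor(stats::runif(n_bg, lo, hi + 1))
    mid <- pmin(pmax(mid, lo), hi)
    data.frame(chrom = rep(config$chrom, n), midpoint = as.integer(mid),
               colocalized = coloc, stringsAsFactors = FALSE)
  })
}

#' Plant motif instances into a genome (ground truth)
#'
#' Writes the consensus sequence (or its reverse complement, on minus-strand
#' instances) into the genome at each placed position, overwriting the
#' existing bases so coordinates stay stable. Overlapping placements are
#' re-drawn up to `max_retries` passes.
#'
#' @param genome Named character vector from [simulate_genome()].
#' @param origins Truth `origin_set` from [place_origins()].
#' @param config A [sim_config()].
#' @param motif Consensus DNA string; must be shorter than
#'   `origin_min_spacing`.
#' @param motif_id Identifier recorded in the truth table.
#' @param max_retries Maximum re-draw passes for overlapping placements.
#' @return List with elements `genome` (edited sequence) and `truth`
#'   (data frame: `chrom`, `start`, `end`, `strand`, `motif_id`,
#'   `colocalized`; 0-based half-open).
#' @export
plant_motifs <- function(genome, origins, config, motif,
                         motif_id = motif, max_retries = 200L) {
  stopifnot(inherits(config, "sim_config"), length(genome) == 1L)
  L <- nchar(motif)
  if (L >= config$origin_min_spacing)
    stopf("motif length (%d) must be smaller than origin_min_spacing (%g)",
          L, config$origin_min_spacing)
  if (anyNA(encode_dna(motif))) stopf("`motif` must contain only A/C/G/T")
  pos <- draw_motif_positions(origins, config, motif_length = L)
  half <- L %/% 2
  start <- pos$midpoint - half

  with_seed(.op_seed(config$seed, 3), {
    # resolve overlaps among planted instances by re-drawing offenders
    tries <- 0L
    repeat {
      o <- order(start)
      overlap <- logical(length(start))
      if (length(start) > 1L) {
        gap_bad <- diff(start[o]) < L
        overlap[o[which(gap_bad) + 1L]] <- TRUE
      }
      if (!any(overlap)) break
      tries <- tries + 1L
      if (tries > max_retries)
        stopf("could not place %d non-overlapping motif instances after %d passes",
              length(start), max_retries)
      idx <- which(overlap)
      redraw_coloc <- idx[pos$colocalized[idx]]
      redraw_bg <- idx[!pos$colocalized[idx]]
      if (length(redraw_coloc)) {
        anchor <- origins$origin[sample.int(nrow(origins),
                                            length(redraw_coloc), replace = TRUE)]
        off <- floor(stats::runif(length(redraw_coloc),
                                  -config$placement_radius,
                                  config$placement_radius + 1))
        start[redraw_coloc] <- pmin(pmax(anchor + off - half, 0L),
                                    config$genome_length - L)
      }
      if (length(redraw_bg))
        start[redraw_bg] <- floor(stats::runif(length(redraw_bg), 0,
                                               config$genome_length - L + 1))
    }
    strand <- sample(c("+", "-"), length(start), replace = TRUE)

    chars <- strsplit(genome[[1L]], "", fixed = TRUE)[[1L]]
    fwd <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
    rev_ <- strsplit(reverse_complement(motif), "", fixed = TRUE)[[1L]]
    for (i in seq_along(start)) {
      span <- (start[i] + 1L):(start[i] + L)
      chars[span] <- if (strand[i] == "+") fwd else rev_
    }
    truth <- data.frame(chrom = pos$chrom, start = as.integer(start),
                        end = as.integer(start + L), strand = strand,
                        motif_id = motif_id, colocalized = pos$colocalized,
                        stringsAsFactors = FALSE)
    list(genome = stats::setNames(paste(chars, collapse = ""), names(genome)),
         truth = truth)
  })
}

#' Simulate divergent strand-specific nascent-transcription coverage
#'
#' Each origin receives `reads_per_origin / 2` plus-strand reads at
#' `origin + offset` and the same number of minus-strand reads at
#' `origin - offset`, with `offset` geometric (support 1, 2, ...) with mean
#' `read_offset_scale`. Uniform noise reads are added on both strands at
#' `noise_read_rate` reads per base.
#'
#' @param origins An `origin_set` (typically truth origins).
#' @param config A [sim_config()].
#' @return A [strand_coverage()] object over the simulated chromosome.
#' @export
simulate_nascent_coverage <- function(origins, config) {
  stopifnot(inherits(config, "sim_config"))
  len <- config$genome_length
  add_reads <- function(track, positions) {
    positions <- positions[positions >= 0 & positions < len]
    if (length(positions)) {
      counts <- tabulate(positions + 1L, nbins = len)
      track + counts
    } else track
  }
  with_seed(.op_seed(config$seed, 4), {
    plus <- integer(len); minus <- integer(len)
    k <- config$reads_per_origin %/% 2L
    p <- 1 / config$read_offset_scale
    for (orig in origins$origin) {
      if (k > 0) {
        plus <- add_reads(plus, orig + stats::rgeom(k, p) + 1L)
        minus <- add_reads(minus, orig - stats::rgeom(k, p) - 1L)
      }
    }
    n_noise <- stats::rpois(2L, config$noise_read_rate * len)
    if (n_noise[1L] > 0)
      plus <- add_reads(plus, floor(stats::runif(n_noise[1L], 0, len)))
    if (n_noise[2L] > 0)
      minus <- add_reads(minus, floor(stats::runif(n_noise[2L], 0, len)))
    strand_coverage(
      plus = stats::setNames(list(plus), config$chrom),
      minus = stats::setNames(list(minus), config$chrom),
      chrom_sizes = stats::setNames(len, config$chrom))
  })
}

#' Per-nucleus simulation configuration
#'
#' Defaults mirror the study conditions of the single-nucleus contrasts:
#' 3000 nuclei per group, accessibility rate ratio 1.52 and expression
#' ratio 1.91 between groups, negative-binomial dispersion 0.5, and
#' sequencing depth lognormal around 5000 counts.
#'
#' @param n_nuclei_per_group Nuclei per group.
#' @param depth_log_mean,depth_log_sd Log-scale parameters of the lognormal
#'   depth distribution.
#' @param baseline_access_rate Probability that a reference-group nucleus at
#'   mean depth has any accessible fragment in the region, in (0, 1).
#' @param access_fold_change Accessibility rate ratio (group b / group a) at
#'   mean depth.
#' @param access_depth_coef Logistic coefficient on centered log-depth.
#' @param baseline_expr_mean Expected UMI count per reference-group nucleus
#'   at mean depth.
#' @param expr_fold_change Expression ratio (group b / group a).
#' @param nb_dispersion Negative-binomial size parameter (variance
#'   `mu + mu^2 / nb_dispersion`); larger is closer to Poisson.
#' @param group_variable Which metadata column carries the contrast:
#'   `"disease"` (control vs IPF) or `"genotype"` (GG vs TT).
#' @param seed Integer seed.
#' @return A validated list of class `nucleus_sim_config`.
#' @export
nucleus_sim_config <- function(n_nuclei_per_group = 3000,
                               depth_log_mean = log(5000), depth_log_sd = 0.5,
                               baseline_access_rate = 0.2,
                               access_fold_change = 1.52,
                               access_depth_coef = 0.5,
                               baseline_expr_mean = 5,
                               expr_fold_change = 1.91,
                               nb_dispersion = 0.5,
                               group_variable = c("disease", "genotype"),
                               seed = 1) {
  group_variable <- match.arg(group_variable)
  if (!is_count(n_nuclei_per_group) || n_nuclei_per_group < 1)
    stopf("`n_nuclei_per_group` must be a positive integer")
  if (!is_number(baseline_access_rate) ||
      baseline_access_rate <= 0 || baseline_access_rate >= 1)
    stopf("`baseline_access_rate` must be in (0, 1)")
  if (!is_number(access_fold_change) || access_fold_change <= 0)
    stopf("`access_fold_change` must be positive")
  if (baseline_access_rate * access_fold_change >= 1)
    stopf("access rate in group b (%g) must stay below 1",
          baseline_access_rate * access_fold_change)
  if (!is_number(expr_fold_change) || expr_fold_change <= 0)
    stopf("`expr_fold_change` must be positive")
  if (!is_number(nb_dispersion) || nb_dispersion <= 0)
    stopf("`nb_dispersion` must be positive")
  if (!is_number(baseline_expr_mean) || baseline_expr_mean <= 0)
    stopf("`baseline_expr_mean` must be positive")
  structure(list(n_nuclei_per_group = as.integer(n_nuclei_per_group),
                 depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
                 baseline_access_rate = baseline_access_rate,
                 access_fold_change = access_fold_change,
                 access_depth_coef = access_depth_coef,
                 baseline_expr_mean = baseline_expr_mean,
                 expr_fold_change = expr_fold_change,
                 nb_dispersion = nb_dispersion,
                 group_variable = group_variable, seed = seed),
            class = "nucleus_sim_config")
}

#' Simulate a per-nucleus feature-count table (ground truth)
#'
#' Depth is lognormal; the accessibility indicator is Bernoulli with a
#' logit linear in group and centered log-depth, calibrated so the rate
#' ratio at mean depth equals `access_fold_change`; the expression count is
#' negative binomial with mean proportional to depth and the group fold
#' change, and dispersion `nb_dispersion`.
#'
#' @param config A [nucleus_sim_config()].
#' @return Data frame with columns `nucleus_id`, `sample_id`, `disease`,
#'   `genotype`, `cell_type`, `total_counts`, `enhancer_fragments` (0/1
#'   accessibility indicator), `gene_umis`. The true simulation parameters
#'   are attached as `attr(, "truth")`.
#' @export
simulate_nucleus_table <- function(config) {
  stopifnot(inherits(config, "nucleus_sim_config"))
  n <- config$n_nuclei_per_group
  with_seed(.op_seed(config$seed, 5), {
    group <- rep(c(0L, 1L), each = n)
    depth <- stats::rlnorm(2L * n, config$depth_log_mean, config$depth_log_sd)
    depth <- pmax(1, round_half_up(depth))

    b0 <- stats::qlogis(config$baseline_access_rate)
    b1 <- stats::qlogis(config$baseline_access_rate *
                          config$access_fold_change) - b0
    eta <- b0 + b1 * group +
      config$access_depth_coef * (log(depth) - config$depth_log_mean)
    accessible <- stats::rbinom(2L * n, 1L, stats::plogis(eta))

    mu <- depth / exp(config$depth_log_mean) * config$baseline_expr_mean *
      ifelse(group == 1L, config$expr_fold_change, 1)
    umis <- stats::rnbinom(2L * n, mu = mu, size = config$nb_dispersion)

    disease <- if (config$group_variable == "disease")
      c("control", "IPF")[group + 1L] else rep("IPF", 2L * n)
    genotype <- if (config$group_variable == "genotype")
      c("GG", "TT")[group + 1L] else rep("GG", 2L * n)
    tab <- data.frame(
      nucleus_id = sprintf("nuc%05d", seq_len(2L * n)),
      sample_id = paste0("sample_", group + 1L),
      disease = disease, genotype = genotype,
      cell_type = rep("secretory", 2L * n),
      total_counts = as.integer(depth),
      enhancer_fragments = as.integer(accessible),
      gene_umis = as.integer(umis),
      stringsAsFactors = FALSE)
    attr(tab, "truth") <- config
    tab
  })
}

#' Simulate a tiled MNase-qPCR Ct table (ground truth)
#'
#' For each amplicon, `Ct_digested = Ct_undigested - log2(protection) +
#' Normal(0, noise_sd)`, with undigested Ct values drawn near a fixed
#' plateau. Higher protection (nucleosome occupancy) leaves more intact
#' template after digestion and therefore a lower digested Ct.
#'
#' @param protection_profile Positive per-amplicon protection values.
#' @param noise_sd Ct noise standard deviation (cycles).
#' @param seed Integer seed.
#' @param n_replicates Replicates per amplicon.
#' @param midpoints Optional amplicon midpoints (default 100 bp tiling).
#' @param undigested_ct Plateau Ct for undigested template.
#' @return Data frame with columns `amplicon_id`, `midpoint`, `replicate`,
#'   `Ct_digested`, `Ct_undigested`; the planted profile is attached as
#'   `attr(, "truth")`.
#' @export
simulate_mnase_ct <- function(protection_profile, noise_sd = 0.2, seed = 1,
                              n_replicates = 4L, midpoints = NULL,
                              undigested_ct = 20) {
  if (!is.numeric(protection_profile) || !length(protection_profile) ||
      any(protection_profile <= 0))
    stopf("`protection_profile` must contain positive values")
  m <- length(protection_profile)
  midpoints <- midpoints %||% (seq_len(m) * 100L)
  if (length(midpoints) != m || is.unsorted(midpoints, strictly = TRUE))
    stopf("`midpoints` must be strictly increasing, one per amplicon")
  with_seed(.op_seed(seed, 6), {
    grid <- expand.grid(amplicon = seq_len(m), replicate = seq_len(n_replicates))
    ct_un <- undigested_ct + stats::rnorm(nrow(grid), 0, noise_sd / 4)
    ct_dig <- ct_un - log2(protection_profile[grid$amplicon]) +
      stats::rnorm(nrow(grid), 0, noise_sd)
    tab <- data.frame(
      amplicon_id = sprintf("amp%02d", grid$amplicon),
      midpoint = midpoints[grid$amplicon],
      replicate = grid$replicate,
      Ct_digested = ct_dig, Ct_undigested = ct_un,
      stringsAsFactors = FALSE)
    attr(tab, "truth") <- protection_profile
    tab
  })
}
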