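# End-to-end demo pipeline on synthetic data: simulate -> scan ->
# call-origins -> MD -> differential MD -> single-nucleus contrasts ->
# MNase profile, with one seeded config and a checksum manifest.

.default_pipeline_config <- function() {
  list(
    seed = 1,
    stages = list(simulate = TRUE, scan = TRUE, call_origins = TRUE,
                  md = TRUE, diff_md = TRUE, sn_compare = TRUE,
                  mnase = TRUE),
    # 10 bp motif: the smallest attainable scan p-value is 4^-L, so motifs
    # shorter than 9 bp cannot reach the 1e-5 cutoff
    scan = list(pvalue = 1e-5, pseudocount = 0.25,
                motif = "TGACGTCATC", certainty = 0.97),
    md = list(r = 150, R = 1500, alpha = 1e-4, n_bins = 100),
    caller = list(min_reads = 20, max_separation = 300,
                  smoothing_halfwidth = 30, merge_distance = 150),
    simulation = list(genome_length = 2e5, gc_fraction = 0.5,
                      n_origins = 20, origin_min_spacing = 3000,
                      n_motif_instances = 300, colocalized_fraction = 0.5,
                      placement_radius = 150, reads_per_origin = 200,
                      read_offset_scale = 60, noise_read_rate = 0),
    nuclei = list(n_nuclei_per_group = 1000, baseline_access_rate = 0.2,
                  access_fold_change = 1.52, expr_fold_change = 1.91,
                  nb_dispersion = 0.5),
    mnase = list(protection_profile = c(1, 2, 4, 2, 0.5, 0.25, 0.5, 2, 4, 2),
                 noise_sd = 0.2, reference_amplicon = "amp01")
  )
}

# Recursively merge user values over defaults, rejecting unknown keys.
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s)%s: %s",
          if (nzchar(path)) paste0(" under '", path, "'") else "",
          paste(unknown, collapse = ", "))
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])))
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       paste0(path, key))
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Pipeline configuration with documented defaults
#'
#' Defaults: MD radii `r = 150`, `R = 1500`, differential-MD `alpha =
#' 1e-4`, scan `pvalue = 1e-5`, caller `min_reads = 20`,
#' `max_separation = 300`, `smoothing_halfwidth = 30`,
#' `merge_distance = 150`. Unknown keys are rejected.
#'
#' @param ... Named overrides, nested as in the default structure (e.g.
#'   `md = list(r = 100)`).
#' @return A nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  structure(.merge_config(.default_pipeline_config(), user),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] keys.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  structure(.merge_config(.default_pipeline_config(), user),
            class = "pipeline_config")
}

#' Run the full demo pipeline on synthetic data
#'
#' Simulates a genome with planted eRNA origins and motif instances plus
#' divergent nascent coverage, scans for the motif at the calibrated
#' p-value threshold, calls origins from the coverage, computes MD against
#' both the called origins (co-localized condition) and a matched null
#' motif placement, tests the difference, runs the single-nucleus
#' accessibility/expression contrasts, and converts a simulated tiled Ct
#' table into a protection profile. All outputs are written under
#' `out_dir` and listed in `manifest.tsv` with MD5 checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the manifest data frame and the in-memory
#'   stage results.
#' @export
run_demo <- function(config = pipeline_config(), out_dir = tempfile("ernamd_demo_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  results <- list()
  emit <- function(path) { paths[[length(paths) + 1L]] <<- path; path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  on <- function(name) isTRUE(config$stages[[name]])

  sim_cfg <- do.call(sim_config, c(config$simulation, list(seed = config$seed)))

  if (on("simulate")) {
    results$sim <- stage("synthetic_data", {
      genome <- simulate_genome(sim_cfg)
      origins <- place_origins(sim_cfg)
      planted <- plant_motifs(genome, origins, sim_cfg,
                              motif = config$scan$motif)
      cov <- simulate_nascent_coverage(origins, sim_cfg)
      write_fasta(planted$genome, emit(file.path(out_dir, "genome.fa")))
      write_origins(origins, emit(file.path(out_dir, "origins_truth.bed")))
      write_bed(cbind(planted$truth,
                      name = planted$truth$motif_id, score = 0),
                emit(file.path(out_dir, "motifs_truth.bed")))
      write_bedgraph(cov, emit(file.path(out_dir, "coverage_plus.bedGraph")),
                     emit(file.path(out_dir, "coverage_minus.bedGraph")))
      chrom_sizes_path <- emit(file.path(out_dir, "chrom.sizes"))
      utils::write.table(
        data.frame(names(cov$chrom_sizes), unname(cov$chrom_sizes)),
        chrom_sizes_path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
      list(genome = planted$genome, origins = origins,
           truth = planted$truth, coverage = cov)
    })
  }

  if (on("scan")) {
    results$scan <- stage("pwm_scan", {
      motif_pwm <- pwm_from_consensus(config$scan$motif,
                                      certainty = config$scan$certainty,
                                      pseudocount = config$scan$pseudocount)
      tab <- log_odds(motif_pwm)
      thr <- threshold_from_pvalue(tab, pvalue = config$scan$pvalue)
      hits <- scan_sequences(results$sim$genome, tab, thr)
      write_bed(cbind(hits, name = hits$motif_id),
                emit(file.path(out_dir, "motif_hits.bed")))
      list(pwm = motif_pwm, threshold = thr, hits = hits)
    })
  }

  if (on("call_origins")) {
    results$origins <- stage("erna_caller", {
      called <- do.call(call_origins,
                        c(list(results$sim$coverage), config$caller))
      write_origins(called, emit(file.path(out_dir, "origins_called.bed")),
                    audit_path = emit(file.path(out_dir, "origins_audit.tsv")))
      called
    })
  }

  if (on("md")) {
    results$md <- stage("md_score", {
      origins <- results$origins %||% results$sim$origins
      dist <- motif_distances(results$scan$hits, origins, R = config$md$R)
      md <- compute_md(dist, r = config$md$r, R = config$md$R)
      utils::write.table(md, emit(file.path(out_dir, "md_scores.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bc <- barcode_matrix(dist, R = config$md$R, n_bins = config$md$n_bins)
      utils::write.table(as.data.frame(unclass(bc)),
                         emit(file.path(out_dir, "barcode_matrix.tsv")),
                         sep = "\t", quote = FALSE, row.names = TRUE)
      list(distances = dist, md = md, barcode = bc)
    })
  }

  if (on("diff_md")) {
    results$diff_md <- stage("md_score_diff", {
      # matched null condition: same genome and origin geometry, no
      # co-localization
      null_cfg <- sim_config(
        genome_length = sim_cfg$genome_length,
        gc_fraction = sim_cfg$gc_fraction,
        n_origins = sim_cfg$n_origins,
        origin_min_spacing = sim_cfg$origin_min_spacing,
        n_motif_instances = sim_cfg$n_motif_instances,
        colocalized_fraction = 0,
        placement_radius = sim_cfg$placement_radius,
        seed = config$seed + 1)
      null_pos <- draw_motif_positions(results$sim$origins, null_cfg,
                                       motif_length = nchar(config$scan$motif))
      null_inst <- data.frame(chrom = null_pos$chrom,
                              start = null_pos$midpoint,
                              end = null_pos$midpoint + 1L,
                              motif_id = config$scan$motif)
      origins <- results$origins %||% results$sim$origins
      md_null <- compute_md(motif_distances(null_inst, origins,
                                            R = config$md$R),
                            r = config$md$r, R = config$md$R)
      dm <- diff_md(results$md$md, md_null, alpha = config$md$alpha)
      utils::write.table(dm, emit(file.path(out_dir, "diff_md.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dm
    })
  }

  if (on("sn_compare")) {
    results$sn <- stage("sn_compare", {
      ncfg <- do.call(nucleus_sim_config,
                      c(config$nuclei, list(seed = config$seed + 2)))
      tab <- simulate_nucleus_table(ncfg)
      write_nucleus_table(tab, emit(file.path(out_dir, "nucleus_table.tsv")))
      sub <- select_nuclei(tab, cell_types = "secretory")
      acc <- diff_accessibility(sub, "enhancer_fragments", "disease")
      expr <- diff_expression(sub, "gene_umis", "disease")
      res <- adjust_bonferroni(rbind(acc, expr))
      utils::write.table(res, emit(file.path(out_dir, "sn_results.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  if (on("mnase")) {
    results$mnase <- stage("mnase_profile", {
      ct <- simulate_mnase_ct(config$mnase$protection_profile,
                              noise_sd = config$mnase$noise_sd,
                              seed = config$seed + 3)
      utils::write.table(ct, emit(file.path(out_dir, "mnase_ct.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      prof <- relative_protection(ct, config$mnase$reference_amplicon)
      utils::write.table(prof,
                         emit(file.path(out_dir, "mnase_protection.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      prof
    })
  }

  manifest <- data.frame(
    file = basename(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths))),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}
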