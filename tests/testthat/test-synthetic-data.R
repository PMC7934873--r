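# Ground-truth generators: genome, origins, planted motifs, divergent
# coverage, nucleus tables, tiled Ct values.

test_that("simulated genomes honor length, composition and determinism", {
  cfg <- sim_config(genome_length = 1, gc_fraction = 0, seed = 1)
  expect_true(simulate_genome(cfg) %in% c("A", "T"))

  cfg2 <- sim_config(genome_length = 100000, gc_fraction = 0.5, seed = 7)
  g <- simulate_genome(cfg2)
  expect_equal(unname(nchar(g)), 100000)
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))  # 3 binomial SDs

  expect_identical(g, simulate_genome(cfg2))  # seeded determinism
  expect_error(sim_config(genome_length = 0), "positive integer")
})

test_that("origin placement respects spacing, bounds and feasibility", {
  cfg <- sim_config(genome_length = 10000, n_origins = 1, seed = 2)
  o <- place_origins(cfg)
  expect_equal(nrow(o), 1L)
  expect_true(o$origin >= cfg$placement_radius &&
                o$origin < cfg$genome_length - cfg$placement_radius)

  bad <- sim_config(genome_length = 5000, n_origins = 5,
                    origin_min_spacing = 2000, seed = 1)
  expect_error(place_origins(bad), "infeasible")

  cfg3 <- sim_config(genome_length = 100000, n_origins = 10,
                     origin_min_spacing = 3000, seed = 5)
  o3 <- place_origins(cfg3)
  expect_gte(min(diff(sort(o3$origin))), 3000)
})

test_that("motif planting controls co-localization and edits the genome in place", {
  cfg <- sim_config(genome_length = 50000, n_origins = 10,
                    origin_min_spacing = 3000, n_motif_instances = 100,
                    colocalized_fraction = 1, placement_radius = 150,
                    seed = 4)
  genome <- simulate_genome(cfg)
  origins <- place_origins(cfg)
  res <- plant_motifs(genome, origins, cfg, motif = "TGACGTCA")
  expect_equal(unname(nchar(res$genome)), unname(nchar(genome)))
  mids <- floor((res$truth$start + res$truth$end) / 2)
  nearest <- vapply(mids, function(m) min(abs(origins$origin - m)), numeric(1))
  expect_lte(max(nearest), 150)  # every instance within the radius
  expect_true(all(res$truth$colocalized))

  # planted spans read back as the consensus (or its reverse complement)
  for (i in sample(nrow(res$truth), 10)) {
    span <- unname(substr(res$genome, res$truth$start[i] + 1,
                          res$truth$end[i]))
    expected <- if (res$truth$strand[i] == "+") "TGACGTCA"
                else reverse_complement("TGACGTCA")
    expect_identical(span, expected)
  }

  # instances do not overlap one another
  o <- order(res$truth$start)
  expect_gte(min(diff(res$truth$start[o])), 8)

  # colocalized flag count equals the rounded fraction
  cfg2 <- sim_config(genome_length = 200000, n_origins = 20,
                     n_motif_instances = 1000, colocalized_fraction = 0.5,
                     seed = 4)
  pos <- draw_motif_positions(place_origins(cfg2), cfg2, motif_length = 8)
  expect_equal(sum(pos$colocalized), 500)
})

test_that("uniform placement yields the window-coverage hit proportion", {
  cfg <- sim_config(genome_length = 1e6, n_origins = 30,
                    n_motif_instances = 20000, colocalized_fraction = 0,
                    seed = 9)
  origins <- place_origins(cfg)
  pos <- draw_motif_positions(origins, cfg, motif_length = 8)
  near <- vapply(pos$midpoint, function(m)
    any(abs(origins$origin - m) <= 150), logical(1))
  p_exp <- nrow(origins) * 301 / 1e6
  expect_lt(abs(mean(near) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 20000))
})

test_that("divergent coverage is strand separated with geometric offsets", {
  cfg0 <- sim_config(genome_length = 10000, n_origins = 1,
                     reads_per_origin = 0, noise_read_rate = 0, seed = 1)
  cov0 <- simulate_nascent_coverage(place_origins(cfg0), cfg0)
  expect_equal(sum(cov0$plus$chrS), 0)
  expect_equal(sum(cov0$minus$chrS), 0)

  cfg <- sim_config(genome_length = 10000, n_origins = 1,
                    origin_min_spacing = 3000, reads_per_origin = 10000,
                    read_offset_scale = 60, noise_read_rate = 0, seed = 8)
  origins <- origin_set(data.frame(chrom = "chrS", origin = 5000L))
  cov <- simulate_nascent_coverage(origins, cfg)
  plus <- cov$plus$chrS; minus <- cov$minus$chrS
  expect_equal(sum(plus[1:5001]), 0)     # plus mass strictly downstream
  expect_equal(sum(minus[5001:10000]), 0)  # minus mass strictly upstream

  # mean plus-strand offset ~ read_offset_scale within 3 SEs
  pos <- rep(seq_along(plus) - 1L, plus)
  offs <- pos - 5000
  se <- sqrt(60 * 59) / sqrt(length(offs))  # geometric sd ~ sqrt(q)/p
  expect_lt(abs(mean(offs) - 60), 3 * se)
})

test_that("nucleus tables encode the configured group effects", {
  # null config: groups exchangeable
  cfg <- nucleus_sim_config(n_nuclei_per_group = 2000,
                            access_fold_change = 1, expr_fold_change = 1,
                            seed = 3)
  tab <- simulate_nucleus_table(cfg)
  expect_equal(nrow(tab), 4000)
  g <- tab$disease == "IPF"
  r_acc <- mean(tab$enhancer_fragments[g]) / mean(tab$enhancer_fragments[!g])
  expect_lt(abs(r_acc - 1), 0.25)
  r_expr <- mean(tab$gene_umis[g]) / mean(tab$gene_umis[!g])
  expect_lt(abs(r_expr - 1), 0.25)

  # near-Poisson limit: variance/mean of counts approaches 1
  cfgp <- nucleus_sim_config(n_nuclei_per_group = 3000, nb_dispersion = 1e6,
                             depth_log_sd = 1e-9, expr_fold_change = 1,
                             seed = 5)
  tp <- simulate_nucleus_table(cfgp)
  vm <- stats::var(tp$gene_umis) / mean(tp$gene_umis)
  expect_lt(abs(vm - 1), 0.15)

  expect_error(nucleus_sim_config(n_nuclei_per_group = 0), "positive")
  expect_error(nucleus_sim_config(nb_dispersion = -1), "positive")
})

test_that("tiled Ct simulation follows the log2 protection model", {
  flat <- simulate_mnase_ct(rep(1, 5), noise_sd = 0, seed = 2)
  expect_equal(flat$Ct_digested, flat$Ct_undigested)

  prof <- simulate_mnase_ct(c(1, 4, 1), noise_sd = 0, seed = 2)
  amp2 <- prof[prof$amplicon_id == "amp02", ]
  expect_equal(amp2$Ct_undigested - amp2$Ct_digested, rep(2, 4))  # log2(4)

  expect_error(simulate_mnase_ct(c(1, 0, 2)), "positive")
})
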