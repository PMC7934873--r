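# Single-nucleus pseudo-bulk contrasts: selection, logistic accessibility,
# negative binomial expression, Bonferroni adjustment, pseudobulk tracks.

make_table <- function(n = 200, seed = 1) {
  tab <- simulate_nucleus_table(
    nucleus_sim_config(n_nuclei_per_group = n, seed = seed))
  # diversify labels for the selection tests
  tab$cell_type <- rep_len(c("secretory", "ciliated", "basal", "secretory"),
                           nrow(tab))
  tab
}

test_that("nucleus selection filters and validates labels", {
  tab <- make_table()
  sec <- select_nuclei(tab, cell_types = "secretory")
  expect_true(all(sec$cell_type == "secretory"))

  epi <- c("secretory", "ciliated", "basal")
  all_epi <- select_nuclei(tab, cell_types = epi)
  non_sec <- select_nuclei(tab, cell_types = setdiff(epi, "secretory"))
  expect_equal(nrow(all_epi) - nrow(sec), nrow(non_sec))  # set difference

  expect_error(select_nuclei(tab, cell_types = "goblet"),
               "unknown cell type.*available")
  expect_error(select_nuclei(tab, disease = "asthma"), "unknown disease")

  ipf_sec <- select_nuclei(tab, cell_types = "secretory", disease = "IPF")
  expect_true(all(ipf_sec$disease == "IPF"))
})

test_that("nucleus tables round-trip through TSV", {
  tab <- make_table(50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_nucleus_table(tab, path)
  back <- read_nucleus_table(path)
  expect_equal(back$total_counts, tab$total_counts)
  expect_equal(back$gene_umis, tab$gene_umis)
})

test_that("accessibility contrast recovers a planted rate ratio", {
  tab <- simulate_nucleus_table(
    nucleus_sim_config(n_nuclei_per_group = 3000, access_fold_change = 1.5,
                       seed = 23))
  res <- diff_accessibility(tab, "enhancer_fragments", "disease")
  expect_gt(res$fold_change, 1.35)
  expect_lt(res$fold_change, 1.65)
  expect_lt(res$p, 1e-6)
  expect_equal(res$n_a, 3000L)
  expect_equal(res$n_b, 3000L)
})

test_that("accessibility contrast is null-calibrated under permuted labels", {
  tab <- simulate_nucleus_table(
    nucleus_sim_config(n_nuclei_per_group = 2000, access_fold_change = 1,
                       expr_fold_change = 1, seed = 31))
  res <- diff_accessibility(tab, "enhancer_fragments", "disease")
  expect_lt(abs(res$fold_change - 1), 0.2)
  expect_gt(res$p, 1e-3)
})

test_that("an all-zero group stays finite and is flagged degenerate", {
  tab <- make_table(100, seed = 2)
  tab$enhancer_fragments[tab$disease == "control"] <- 0L
  res <- diff_accessibility(tab, "enhancer_fragments", "disease")
  expect_true(is.finite(res$fold_change))
  expect_true(res$degenerate)
})

test_that("expression contrast recovers the planted fold change and absorbs depth", {
  tab <- simulate_nucleus_table(
    nucleus_sim_config(n_nuclei_per_group = 3000, expr_fold_change = 1.91,
                       nb_dispersion = 0.5, seed = 29))
  res <- diff_expression(tab, "gene_umis", "disease")
  expect_lt(abs(res$fold_change - 1.91) / 1.91, 0.1)
  expect_lt(res$p, 1e-10)

  # doubling all depths with counts fixed leaves the fold change unchanged
  tab2 <- tab
  tab2$total_counts <- tab$total_counts * 2L
  res2 <- diff_expression(tab2, "gene_umis", "disease")
  expect_equal(res2$fold_change, res$fold_change, tolerance = 1e-6)

  # null fold change near 1
  tab0 <- simulate_nucleus_table(
    nucleus_sim_config(n_nuclei_per_group = 2000, expr_fold_change = 1,
                       seed = 37))
  res0 <- diff_expression(tab0, "gene_umis", "disease")
  expect_lt(abs(res0$fold_change - 1), 0.15)
})

test_that("swapping group direction inverts fold changes", {
  tab <- simulate_nucleus_table(
    nucleus_sim_config(n_nuclei_per_group = 1500, seed = 41))
  fwd_a <- diff_accessibility(tab, "enhancer_fragments", "disease")
  fwd_e <- diff_expression(tab, "gene_umis", "disease")
  swapped <- tab
  # relabel so the alphabetical reference flips: control -> z_control
  swapped$disease <- ifelse(tab$disease == "control", "z_control", "IPF")
  rev_a <- diff_accessibility(swapped, "enhancer_fragments", "disease")
  rev_e <- diff_expression(swapped, "gene_umis", "disease")
  expect_equal(fwd_a$fold_change * rev_a$fold_change, 1, tolerance = 1e-9)
  expect_equal(fwd_e$fold_change * rev_e$fold_change, 1, tolerance = 1e-6)
})

test_that("label permutation yields approximately uniform p-values", {
  set.seed(43)
  tab <- simulate_nucleus_table(
    nucleus_sim_config(n_nuclei_per_group = 250, seed = 47))
  n_perm <- 400
  p_acc <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- tab
    perm$disease <- sample(tab$disease)
    p_acc[i] <- diff_accessibility(perm, "enhancer_fragments", "disease")$p
  }
  expect_gt(stats::ks.test(p_acc, "punif")$p.value, 0.01)

  n_perm_nb <- 200
  p_expr <- numeric(n_perm_nb)
  for (i in seq_len(n_perm_nb)) {
    perm <- tab
    perm$disease <- sample(tab$disease)
    p_expr[i] <- diff_expression(perm, "gene_umis", "disease")$p
  }
  expect_gt(stats::ks.test(p_expr, "punif")$p.value, 0.01)
})

test_that("Bonferroni adjustment caps and preserves order", {
  res <- data.frame(p = c(0.01, 0.2, 0.03))
  adj <- adjust_bonferroni(res, n_tests = 10)
  expect_equal(adj$p_adj, c(0.1, 1, 0.3))
  adj1 <- adjust_bonferroni(data.frame(p = 0.04), n_tests = 1)
  expect_equal(adj1$p_adj, 0.04)
  expect_error(adjust_bonferroni(res, n_tests = 2), "at least")
})

test_that("pseudobulk profiles aggregate and normalize fragment coverage", {
  sub <- data.frame(nucleus_id = "n1", sample_id = "s", disease = "IPF",
                    genotype = "GG", cell_type = "secretory",
                    total_counts = 1000L)
  frags <- data.frame(nucleus_id = "n1", chrom = "chr1",
                      start = 100L, end = 200L)
  region <- list(chrom = "chr1", start = 0L, end = 300L)
  prof <- pseudobulk_profile(sub, frags, region)
  raw <- attr(prof, "raw")
  expect_equal(sum(raw), 100)
  expect_equal(raw[101:200], rep(1, 100))
  expect_equal(prof$coverage[101:200], rep(1e4, 100))  # per 1e4 nuclei

  # duplicated nucleus doubles raw coverage; normalization cancels it
  sub2 <- rbind(sub, sub)
  prof2 <- pseudobulk_profile(sub2, frags, region)
  expect_equal(attr(prof2, "raw"), 2 * raw)
  expect_equal(prof2$coverage, prof$coverage)

  # empty subset is flagged and zero
  expect_warning(prof0 <- pseudobulk_profile(sub[0, ], frags, region),
                 "empty")
  expect_true(all(prof0$coverage == 0))
  expect_true(isTRUE(attr(prof0, "flagged_empty")))
})
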