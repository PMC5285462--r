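test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(deletion_fraction = 1.5), "proportion")
  expect_error(sim_config(size_confounding_factor = 0.5), ">= 1")
  expect_warning(sim_config(cnv_length_log_mean = log(5e4)), "100 kb")
})

test_that("gene annotation is sorted, non-overlapping, and within bounds", {
  cfg <- sim_config(n_genes = 100, n_chroms = 2, seed = 51)
  g <- gen_gene_annotation(cfg)
  expect_equal(nrow(g), 100)
  expect_equal(as.integer(table(g$chrom)), c(50L, 50L))
  expect_false(any(duplicated(g$gene_id)))
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    expect_true(!is.unsorted(gc$start))
    expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))  # non-overlap
    expect_true(all(gc$start >= 1 & gc$end <= cfg$genome_length_per_chrom))
  }
  # single-gene boundary case
  g1 <- gen_gene_annotation(sim_config(n_genes = 1, n_chroms = 1,
                                       genome_length_per_chrom = 1e6))
  expect_equal(nrow(g1), 1)
  expect_true(g1$start > 0 && g1$start < g1$end && g1$end <= 1e6)
  expect_error(gen_gene_annotation(sim_config(n_genes = 1000, n_chroms = 1,
                                              genome_length_per_chrom = 1e5)),
               "too small")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, seed = 52)
  g1 <- gen_gene_annotation(cfg); g2 <- gen_gene_annotation(cfg)
  expect_identical(g1, g2)
  expect_identical(gen_probe_stats(g1, cfg), gen_probe_stats(g1, cfg))
  expect_identical(gen_homology_table(g1, seed = 5),
                   gen_homology_table(g1, seed = 5))
  planted <- g1$gene_id[1:20]
  expect_identical(gen_cnv_cohort(g1, planted, cfg),
                   gen_cnv_cohort(g1, planted, cfg))
})

test_that("homology table hits its configured mapping proportions", {
  cfg <- sim_config(n_genes = 1000, seed = 53)
  g <- gen_gene_annotation(cfg)
  # bijective when nothing is unmapped or multimapped
  bij <- gen_homology_table(g, 0, 0, seed = 53)
  expect_equal(nrow(bij), 1000)
  expect_false(any(duplicated(bij$source_gene_id)))
  expect_false(any(duplicated(bij$human_gene_id)))
  # degenerate: everything unmapped
  none <- gen_homology_table(g, 1, 0, seed = 53)
  expect_equal(nrow(none), 0)
  # multimapped flag counts: reproducible and near expectation
  hom <- gen_homology_table(g, 0.1, 0.1, seed = 53)
  n_multi <- sum(table(hom$source_gene_id) > 1)
  expect_equal(n_multi,
               sum(table(gen_homology_table(g, 0.1, 0.1,
                                            seed = 53)$source_gene_id) > 1))
  expect_gt(n_multi, 100 - 3 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(n_multi, 100 + 3 * sqrt(1000 * 0.1 * 0.9))
  expect_error(gen_homology_table(g, 0.6, 0.6), "<= 1")
})

test_that("null probe p-values are uniform; signal genes rank to the top", {
  cfg0 <- sim_config(n_genes = 5000, signal_fraction = 0,
                     frac_ambiguous_probes = 0, seed = 54)
  g0 <- gen_gene_annotation(cfg0)
  pr0 <- gen_probe_stats(g0, cfg0)
  expect_gte(nrow(pr0), 1e4)
  expect_gt(ks.test(pr0$p_mas5, "punif")$p.value, 0.01)
  expect_gt(ks.test(pr0$p_rma, "punif")$p.value, 0.01)
  expect_lt(abs(cor(pr0$p_mas5, pr0$p_rma)), 0.05)

  cfg1 <- sim_config(n_genes = 1000, signal_fraction = 0.05,
                     signal_effect = 3, seed = 55)
  g1 <- gen_gene_annotation(cfg1)
  pr1 <- gen_probe_stats(g1, cfg1)
  truth <- attr(pr1, "signal_genes")
  expect_length(truth, 50)
  hom <- gen_homology_table(g1, 0, 0, seed = 55)
  ranking <- collapse_to_genes(filter_probes(pr1), hom)
  top5 <- select_top_fraction(ranking, 0.05)$members
  recall <- mean(truth %in% top5)
  expect_gt(recall, 5 * 0.05)  # far above the chance rate
  # signal p-value pairs are positively correlated
  sig <- pr1[pr1$source_gene_id %in% sub("^HG", "RG", truth), ]
  expect_gt(cor(log(sig$p_mas5), log(sig$p_rma)), 0.3)
})

test_that("probes-per-gene and ambiguous-probe fractions are respected", {
  cfg <- sim_config(n_genes = 500, probes_per_gene_max = 4,
                    frac_ambiguous_probes = 0.1, seed = 56)
  g <- gen_gene_annotation(cfg)
  pr <- gen_probe_stats(g, cfg)
  per_gene <- table(pr$source_gene_id)
  expect_true(all(per_gene >= 1 & per_gene <= 4))
  expect_equal(length(per_gene), 500)
  frac_na <- mean(is.na(pr$source_gene_id))
  expect_gt(frac_na, 0.05); expect_lt(frac_na, 0.15)
  # probes_per_gene_max = 1: Simes collapse is the identity per gene
  cfg1 <- sim_config(n_genes = 200, probes_per_gene_max = 1,
                     frac_ambiguous_probes = 0, seed = 56)
  pr1 <- gen_probe_stats(gen_gene_annotation(cfg1), cfg1)
  expect_equal(length(unique(pr1$source_gene_id)), nrow(pr1))
})

test_that("CNV cohort structure follows the configuration", {
  sc <- sim_cohort(seed = 57, n_cases = 300, n_controls = 300)
  cfg <- sc$cfg
  expect_equal(nrow(sc$subjects), 600)
  # intercept solving keeps the realized case fraction near the target
  expect_lt(abs(mean(sc$subjects$phenotype) - 0.5), 0.07)
  expect_setequal(unique(sc$subjects$study),
                  sprintf("study%d", 1:cfg$n_studies))
  cn <- sc$cnvs
  expect_true(all(cn$n_probes >= 1))
  expect_true(all(cn$start <= cn$end))
  expect_true(all(cn$end <= cfg$genome_length_per_chrom))
  # probe counts monotone non-decreasing in length at fixed rate
  o <- order(cn$length)
  expect_true(!is.unsorted(cn$n_probes[o]))
  expect_equal(cn$n_probes,
               pmax(1L, as.integer(round(cfg$probes_per_kb * cn$length / 1000))))
})

test_that("planted effect and degenerate cohorts behave as configured", {
  genes <- gen_gene_annotation(sim_config(seed = 58))
  expect_error(gen_cnv_cohort(genes, character(0), sim_config(seed = 58)),
               "empty")
  # zero CNV rate: empty CNV table, all-zero burden, non-estimable fit
  cfg0 <- sim_config(cnvs_per_subject_mean = 0, planted_log_or = 0,
                     n_cases = 50, n_controls = 50, seed = 58)
  coh0 <- gen_cnv_cohort(genes, character(0), cfg0)
  expect_equal(nrow(coh0$cnvs), 0)
  ann0 <- annotate_cnvs(coh0$cnvs, genes)
  b0 <- build_burden_table(coh0$subjects, ann0, genes$gene_id[1:10])
  expect_true(all(b0$set_hits == 0 & b0$total_cnv_kb == 0))
  expect_equal(fit_enrichment(b0)$flag, "constant_predictor")
})

test_that("null cohorts have odds ratio near one for the planted set", {
  # with planted_log_or = 0 the phenotype is independent of gene-set hits
  sc <- sim_cohort(seed = 59, n_cases = 2000, n_controls = 2000,
                   planted_log_or = 0)
  b <- build_burden_table(sc$subjects, sc$annotated, sc$planted)
  carrier <- b$set_hits > 0
  tab <- table(carrier, b$phenotype)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or, 0.75); expect_lt(or, 1.33)
})

test_that("size confounding enlarges case CNVs only", {
  sc <- sim_cohort(seed = 60, n_cases = 500, n_controls = 500,
                   planted_log_or = 0, size_confounding_factor = 1.3)
  cn <- merge(sc$cnvs, sc$subjects, by = "subject_id")
  mean_case <- mean(cn$length[cn$phenotype == 1])
  mean_ctrl <- mean(cn$length[cn$phenotype == 0])
  expect_gt(mean_case / mean_ctrl, 1.2)
})
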