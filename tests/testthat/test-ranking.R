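test_that("fisher_combine matches the closed-form chi-square(4) tail", {
  expect_equal(fisher_combine(1, 1), 1)
  expect_equal(fisher_combine(0.05, 0.05), fisher_closed_form(0.05, 0.05),
               tolerance = 1e-12)
  # spot value: X = -4 ln 0.05 = 11.98293, tail = exp(-X/2)(1+X/2) ~ 0.0175
  expect_equal(fisher_combine(0.05, 0.05), 0.0174786614, tolerance = 1e-7)
  set.seed(11)
  p1 <- runif(2000); p2 <- runif(2000)
  expect_equal(fisher_combine(p1, p2), fisher_closed_form(p1, p2),
               tolerance = 1e-12)
})

test_that("fisher_combine is symmetric, monotone, and validates its domain", {
  set.seed(12)
  a <- runif(100); b <- runif(100)
  expect_equal(fisher_combine(a, b), fisher_combine(b, a))
  # decreasing one input never increases the output
  expect_true(all(fisher_combine(a * 0.5, b) <= fisher_combine(a, b)))
  expect_gte(fisher_combine(0.1, 1.0), fisher_combine(0.1, 0.1))
  expect_error(fisher_combine(0, 0.5), "positive")
  expect_error(fisher_combine(0.5, 1.5), "0, 1")
  expect_warning(fisher_combine(1e-310, 0.5), "clamped")
})

test_that("simes_combine matches brute-force enumeration and its bounds", {
  expect_equal(simes_combine(0.02), 0.02)
  expect_equal(simes_combine(c(0.01, 0.04)), 0.02)
  expect_equal(simes_combine(c(0.5, 0.5, 0.5)), 0.5)
  set.seed(13)
  for (i in 1:500) {
    m <- sample(1:10, 1)
    p <- runif(m)
    s <- simes_combine(p)
    expect_equal(s, simes_brute(p))
    expect_equal(s, simes_combine(sample(p)))  # permutation invariance
    expect_gte(s, min(p))
    expect_lte(s, min(1, m * min(p)))
  }
  expect_error(simes_combine(numeric(0)), "empty")
  expect_error(simes_combine(c(0.5, 0)), "0, 1")
})

test_that("filter_probes removes probes without a unique gene target", {
  pr <- data.frame(probe_id = sprintf("P%d", 1:10),
                   source_gene_id = c(rep("RG1", 4), rep("RG2", 4), NA, ""),
                   p_mas5 = runif(10), p_rma = runif(10),
                   stringsAsFactors = FALSE)
  expect_message(out <- filter_probes(pr), "removed 2")
  expect_equal(nrow(out), 8)
  expect_equal(attr(out, "n_removed"), 2L)
  clean <- pr[1:8, ]
  expect_silent(res <- filter_probes(clean))
  expect_equal(res$probe_id, clean$probe_id)
  expect_warning(filter_probes(pr[0, ]), "empty")
})

test_that("collapse_to_genes composes Fisher then Simes per gene", {
  hom <- data.frame(group_id = c("G1", "G2"),
                    source_gene_id = c("RG1", "RG2"),
                    human_gene_id = c("HG1", "HG2"),
                    stringsAsFactors = FALSE)
  # one gene, one probe: gene p equals the Fisher combination of the pair
  pr1 <- data.frame(probe_id = "P1", source_gene_id = "RG1",
                    p_mas5 = 0.03, p_rma = 0.2, stringsAsFactors = FALSE)
  out1 <- collapse_to_genes(pr1, hom)
  expect_equal(out1$combined_p, fisher_combine(0.03, 0.2))
  expect_equal(out1$human_gene_id, "HG1")

  # multi-probe gene: probe-level Fisher p's are Simes-collapsed
  pr2 <- data.frame(probe_id = c("P1", "P2", "P3"),
                    source_gene_id = c("RG1", "RG1", "RG2"),
                    p_mas5 = c(0.01, 0.2, 0.5),
                    p_rma = c(0.05, 0.1, 0.5), stringsAsFactors = FALSE)
  out2 <- collapse_to_genes(pr2, hom)
  exp_g1 <- simes_combine(c(fisher_combine(0.01, 0.05),
                            fisher_combine(0.2, 0.1)))
  expect_equal(out2$combined_p[out2$human_gene_id == "HG1"], exp_g1)
  expect_equal(out2$rank, seq_len(2))
  expect_true(!is.unsorted(out2$combined_p))
})

test_that("homolog uniqueness is enforced in both directions", {
  pr <- data.frame(probe_id = sprintf("P%d", 1:4),
                   source_gene_id = c("RG1", "RG2", "RG3", "RG4"),
                   p_mas5 = c(0.1, 0.2, 0.3, 0.4),
                   p_rma = c(0.1, 0.2, 0.3, 0.4), stringsAsFactors = FALSE)
  hom <- data.frame(
    group_id = c("G1", "G2", "G2", "G3", "G3"),
    source_gene_id = c("RG1", "RG2", "RG3", "RG4", "RG4"),
    human_gene_id = c("HG1", "HGshared", "HGshared", "HG4a", "HG4b"),
    stringsAsFactors = FALSE)
  out <- collapse_to_genes(pr, hom)
  # RG2, RG3 share one human homolog -> both excluded; RG4 multimaps -> excluded
  expect_equal(out$human_gene_id, "HG1")
  excl <- attr(out, "excluded")
  expect_equal(unname(excl["multimapped"]), 1L)
  expect_equal(unname(excl["shared_human"]), 2L)
  # one-directional mode keeps the shared-human pair
  out1 <- collapse_to_genes(pr, hom, bidirectional = FALSE)
  expect_setequal(out1$human_gene_id, c("HG1", "HGshared"))
})

test_that("select_top_fraction uses floor arithmetic with deterministic ties", {
  scores <- data.frame(human_gene_id = sprintf("HG%03d", 1:200),
                       combined_p = rep(seq(0.001, 0.2, length.out = 40),
                                        each = 5),
                       stringsAsFactors = FALSE)
  gs <- select_top_fraction(scores, 0.05, label = "x")
  expect_s3_class(gs, "gene_set")
  expect_length(gs$members, 10)
  expect_length(select_top_fraction(scores, 1.0)$members, 200)
  # p-ties spanning the cutoff: membership identical across runs
  gs2 <- select_top_fraction(scores[sample(nrow(scores)), ], 0.05)
  expect_equal(sort(gs$members), sort(gs2$members))
  expect_error(select_top_fraction(scores, 0.001), "empty")
  expect_error(select_top_fraction(scores, 0), "0, 1")
})

test_that("null gene-level p-values are conservative-to-uniform", {
  cfg <- sim_config(n_genes = 2000, signal_fraction = 0,
                    frac_ambiguous_probes = 0, seed = 41)
  genes <- gen_gene_annotation(cfg)
  probes <- gen_probe_stats(genes, cfg)
  hom <- gen_homology_table(genes, frac_unmapped = 0, frac_multimapped = 0,
                            seed = 41)
  ranking <- collapse_to_genes(probes, hom)
  ecdf05 <- mean(ranking$combined_p <= 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(ranking))
  expect_lte(ecdf05, 0.05 + 3 * se)
})
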