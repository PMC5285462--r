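test_that("build_burden_table aggregates per subject with distinct gene counts", {
  genes <- tiny_genes()
  # S1 has two CNVs; chr1 CNV hits HG1+HG2, chr2 CNV hits HG4
  ann <- annotate_cnvs(tiny_cnvs(), genes)
  b <- build_burden_table(tiny_subjects(), ann, c("HG00001", "HG00004"))
  expect_equal(nrow(b), 4)
  s1 <- b[b$subject_id == "S1", ]
  expect_equal(s1$set_hits, 2L)
  expect_equal(s1$total_genes_hit, 3L)
  expect_equal(s1$total_cnv_kb, (1101 + 451) / 1000)
  # CNV-free subject S4: zeros, not NAs
  s4 <- b[b$subject_id == "S4", ]
  expect_equal(unlist(s4[, c("set_hits", "total_cnv_kb", "total_genes_hit")]),
               c(set_hits = 0, total_cnv_kb = 0, total_genes_hit = 0))
})

test_that("a gene hit by two CNVs of one subject counts once", {
  genes <- tiny_genes()
  cn <- data.frame(subject_id = "S1", chrom = "chr1",
                   start = c(150, 250), end = c(250, 350),
                   type = "deletion", n_probes = 20L, length = 101,
                   stringsAsFactors = FALSE)
  ann <- annotate_cnvs(cn, genes)
  b <- build_burden_table(tiny_subjects(), ann, "HG00001")
  expect_equal(b$set_hits[b$subject_id == "S1"], 1L)
})

test_that("unknown CNV subjects are a strict error naming the subject", {
  ann <- annotate_cnvs(tiny_cnvs(), tiny_genes())
  subj <- tiny_subjects()[1:2, ]  # S3 missing
  expect_error(build_burden_table(subj, ann, "HG00001"), "S3")
  expect_warning(b <- build_burden_table(subj, ann, "HG00001", strict = FALSE),
                 "S3")
  expect_equal(nrow(b), 2)
})

test_that("covariate-free fit equals the 2x2 log odds ratio analytically", {
  set.seed(31)
  n <- 500
  hit <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * hit))
  b <- data.frame(subject_id = as.character(1:n), phenotype = y,
                  set_hits = hit, total_cnv_kb = 0, total_genes_hit = 0,
                  chip = "c", study = "s", stringsAsFactors = FALSE)
  r <- suppressMessages(fit_enrichment(b, covariates = character(0)))
  tab <- table(hit, y)
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  expect_equal(r$beta, lor, tolerance = 1e-6)
  expect_equal(r$p, 2 * pnorm(-abs(r$z)))
  expect_equal(sign(r$beta), sign(r$z))
  # Wald two-tailed p close to the likelihood-ratio p at this n
  fit1 <- glm(y ~ hit, family = binomial())
  fit0 <- glm(y ~ 1, family = binomial())
  p_lr <- pchisq(fit0$deviance - fit1$deviance, 1, lower.tail = FALSE)
  expect_lt(abs(r$p - p_lr) / p_lr, 0.10)
})

test_that("degenerate designs are flagged, not silently NaN", {
  b <- data.frame(subject_id = as.character(1:20),
                  phenotype = rep(c(0L, 1L), 10),
                  set_hits = 0L, total_cnv_kb = 0, total_genes_hit = 0L,
                  chip = "c", study = "s", stringsAsFactors = FALSE)
  r <- fit_enrichment(b)
  expect_equal(r$flag, "constant_predictor")
  expect_true(is.na(r$beta))
  b2 <- b; b2$phenotype <- 1L; b2$set_hits <- rep(0:1, 10)
  expect_equal(fit_enrichment(b2)$flag, "single_class_outcome")
  # perfect separation
  b3 <- b; b3$set_hits <- b3$phenotype
  r3 <- suppressMessages(fit_enrichment(b3, covariates = character(0)))
  expect_equal(r3$flag, "separation")
})

test_that("single-level covariates are dropped with a message", {
  set.seed(32)
  b <- data.frame(subject_id = as.character(1:100),
                  phenotype = rbinom(100, 1, 0.5),
                  set_hits = rbinom(100, 2, 0.3),
                  total_cnv_kb = runif(100, 0, 500),
                  total_genes_hit = rpois(100, 3),
                  chip = "onlychip", study = sample(c("a", "b"), 100, TRUE),
                  stringsAsFactors = FALSE)
  expect_message(r <- fit_enrichment(b), "chip")
  expect_false(is.na(r$beta))
})

test_that("bonferroni caps at one and respects the family size", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(0.1, 0), ">= 1")
})

test_that("deletion and duplication burden tables sum to the all-CNV table", {
  sc <- sim_cohort(seed = 33, n_cases = 150, n_controls = 150)
  set <- sample(sc$genes$gene_id, 50)
  b_all <- build_burden_table(sc$subjects, sc$annotated, set, "all")
  b_del <- build_burden_table(sc$subjects, sc$annotated, set, "deletion")
  b_dup <- build_burden_table(sc$subjects, sc$annotated, set, "duplication")
  expect_equal(b_del$total_cnv_kb + b_dup$total_cnv_kb, b_all$total_cnv_kb)
  # distinct-gene counts are additive because deletion/duplication CNV sets
  # are disjoint (a gene hit by both strata counts in each)
  expect_true(all(b_del$set_hits + b_dup$set_hits >= b_all$set_hits))
})

test_that("per-gene decomposition agrees with the contingency-table direction", {
  set.seed(34)
  n <- 200
  subjects <- data.frame(subject_id = sprintf("S%03d", 1:n),
                         phenotype = rep(c(1L, 0L), each = n / 2),
                         chip = "c", study = "s", stringsAsFactors = FALSE)
  # gene GA carried by 8 cases and 0 controls; GB by nobody
  carriers <- subjects$subject_id[1:8]
  cn <- data.frame(subject_id = carriers, chrom = "chr1",
                   start = 200, end = 320, type = "deletion",
                   n_probes = 20L, length = 121, stringsAsFactors = FALSE)
  ann <- annotate_cnvs(cn, tiny_genes())
  pg <- suppressMessages(
    per_gene_enrichment(subjects, ann, c("HG00001", "HG00002", "HG00003"),
                        covariates = character(0)))
  ga <- pg[pg$gene_id == "HG00001", ]
  expect_equal(ga$n_carriers, 8)
  expect_equal(ga$n_case_carriers, 8)
  expect_gt(ga$beta, 0)  # direction agrees with the all-case 2x2 table
  gb <- pg[pg$gene_id == "HG00003", ]
  expect_equal(gb$flag, "constant_predictor")
  expect_true(is.na(gb$beta))
})
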