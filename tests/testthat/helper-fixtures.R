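# Small builders shared across the suite. Everything is generated in code;
# seeds are fixed per call site.

# hand-laid annotation on two chromosomes, 1-based inclusive
tiny_genes <- function() {
  data.frame(
    gene_id = c("HG00001", "HG00002", "HG00003", "HG00004", "HG00005"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(200, 1000, 5000, 100, 900),
    end = c(300, 1500, 5400, 450, 1200),
    stringsAsFactors = FALSE
  )
}

tiny_cnvs <- function() {
  data.frame(
    subject_id = c("S1", "S1", "S2", "S3"),
    chrom = c("chr1", "chr2", "chr1", "chr1"),
    start = c(100, 50, 4900, 100),
    end = c(1200, 500, 5100, 199),
    type = c("deletion", "duplication", "deletion", "duplication"),
    n_probes = c(20L, 18L, 16L, 15L),
    stringsAsFactors = FALSE
  ) -> df
  df$length <- df$end - df$start + 1
  df
}

tiny_subjects <- function() {
  data.frame(subject_id = c("S1", "S2", "S3", "S4"),
             phenotype = c(1L, 0L, 1L, 0L),
             chip = c("chipA", "chipA", "chipB", "chipB"),
             study = c("st1", "st2", "st1", "st2"),
             stringsAsFactors = FALSE)
}

# one simulated cohort with its annotation and planted set; the workhorse
# of the calibration/recovery simulations
sim_cohort <- function(seed, ..., planted = NULL) {
  cfg <- sim_config(seed = seed, ...)
  genes <- gen_gene_annotation(cfg)
  if (is.null(planted)) {
    set.seed(cfg$seed + 3L)
    planted <- sort(sample(genes$gene_id,
                           round(cfg$planted_set_fraction * nrow(genes))))
  }
  coh <- gen_cnv_cohort(genes, planted, cfg)
  ann <- annotate_cnvs(filter_cnvs(coh$cnvs, quiet = TRUE), genes)
  list(cfg = cfg, genes = genes, planted = planted,
       subjects = coh$subjects, cnvs = coh$cnvs, annotated = ann,
       truth = coh$truth)
}

# per-base brute-force overlap oracle (1-based inclusive coordinates)
brute_force_hits <- function(cnv_row, genes) {
  hits <- character(0)
  for (k in seq_len(nrow(genes))) {
    if (genes$chrom[k] != cnv_row$chrom) next
    a <- max(cnv_row$start, genes$start[k])
    b <- min(cnv_row$end, genes$end[k])
    if (a <= b) hits <- c(hits, genes$gene_id[k])
  }
  sort(hits)
}

# closed-form chi-square(4) upper tail for the two-p Fisher statistic
fisher_closed_form <- function(p1, p2) {
  x <- -2 * (log(p1) + log(p2))
  exp(-x / 2) * (1 + x / 2)
}

# brute-force Simes: explicit enumeration over order statistics
simes_brute <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vals <- numeric(m)
  for (i in seq_len(m)) vals[i] <- m * ps[i] / i
  min(1, min(vals))
}
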