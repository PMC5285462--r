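#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic test bed: the gene universe, the
#' probe-level expression p-values, and the case-control CNV cohort with a
#' planted gene-set effect. The defaults describe a scaled-down but
#' structurally faithful cohort: three studies, two chip types per cohort,
#' CNV lengths lognormal around 200 kb so that most calls survive the
#' standard >= 100 kb / >= 15 probe reliability filter.
#'
#' @param n_genes number of genes in the annotation universe.
#' @param n_chroms number of chromosomes the genes are spread over.
#' @param genome_length_per_chrom chromosome length in bp.
#' @param n_cases,n_controls target cohort composition.
#' @param cnvs_per_subject_mean Poisson mean number of CNV calls per subject.
#' @param cnv_length_log_mean,cnv_length_log_sd lognormal parameters (log-bp)
#'   of CNV length. The default mean `log(2e5)` puts the bulk of calls above
#'   the 100 kb filter; a warning is issued if the configured median falls
#'   below 100 kb, since the filter would then starve the cohort.
#' @param probes_per_kb array probe density used to derive the supporting
#'   probe count of each CNV call (`round(probes_per_kb * length/1000)`,
#'   floored at 1).
#' @param deletion_fraction fraction of calls that are deletions (the rest
#'   are duplications).
#' @param planted_set_fraction fraction of the gene universe forming the
#'   planted causal gene set.
#' @param planted_log_or log odds ratio per distinct planted-set gene hit by
#'   a subject's filtered CNVs; this is the estimand the downstream burden
#'   regression recovers.
#' @param background_log_or log odds ratio per distinct gene (any gene) hit;
#'   a nonzero value gives every gene set a uniform case-burden bias, the
#'   situation the permutation empirical correction is designed to remove.
#' @param size_confounding_factor multiplicative factor (>= 1) applied to
#'   case CNV lengths after phenotype assignment, inducing a case-control
#'   CNV-size confound.
#' @param n_chip_types,n_studies numbers of chip-type and study strata.
#' @param signal_fraction fraction of genes that are truly differentially
#'   expressed in the synthetic probe tables.
#' @param signal_effect latent normal shift controlling how small the signal
#'   p-values are (in SD units; 3 gives strong, clearly recoverable signal).
#' @param probes_per_gene_max each gene receives 1..probes_per_gene_max
#'   probe sets, uniformly.
#' @param frac_ambiguous_probes fraction of probes annotated as targeting no
#'   unique gene, to exercise probe filtering.
#' @param seed integer seed; the same seed and config give byte-identical
#'   outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000L,
                       n_chroms = 5L,
                       genome_length_per_chrom = 25e6,
                       n_cases = 500L,
                       n_controls = 500L,
                       cnvs_per_subject_mean = 2,
                       cnv_length_log_mean = log(2e5),
                       cnv_length_log_sd = 0.5,
                       probes_per_kb = 0.2,
                       deletion_fraction = 0.5,
                       planted_set_fraction = 0.05,
                       planted_log_or = log(2),
                       background_log_or = 0,
                       size_confounding_factor = 1,
                       n_chip_types = 2L,
                       n_studies = 3L,
                       signal_fraction = 0.05,
                       signal_effect = 3,
                       probes_per_gene_max = 4L,
                       frac_ambiguous_probes = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_chroms = as.integer(n_chroms),
    genome_length_per_chrom = as.numeric(genome_length_per_chrom),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    cnvs_per_subject_mean = as.numeric(cnvs_per_subject_mean),
    cnv_length_log_mean = as.numeric(cnv_length_log_mean),
    cnv_length_log_sd = as.numeric(cnv_length_log_sd),
    probes_per_kb = as.numeric(probes_per_kb),
    deletion_fraction = as.numeric(deletion_fraction),
    planted_set_fraction = as.numeric(planted_set_fraction),
    planted_log_or = as.numeric(planted_log_or),
    background_log_or = as.numeric(background_log_or),
    size_confounding_factor = as.numeric(size_confounding_factor),
    n_chip_types = as.integer(n_chip_types),
    n_studies = as.integer(n_studies),
    signal_fraction = as.numeric(signal_fraction),
    signal_effect = as.numeric(signal_effect),
    probes_per_gene_max = as.integer(probes_per_gene_max),
    frac_ambiguous_probes = as.numeric(frac_ambiguous_probes),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  counts <- c("n_genes", "n_chroms", "n_cases", "n_controls",
              "n_chip_types", "n_studies", "probes_per_gene_max")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L)
      stop_cfg(sprintf("'%s' must be a count >= 1", f))
  }
  props <- c("deletion_fraction", "planted_set_fraction", "signal_fraction",
             "frac_ambiguous_probes")
  for (f in props) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_cfg(sprintf("'%s' must be a proportion in [0, 1]", f))
  }
  if (cfg$cnvs_per_subject_mean < 0)
    stop_cfg("'cnvs_per_subject_mean' must be >= 0")
  if (cfg$size_confounding_factor < 1)
    stop_cfg("'size_confounding_factor' must be >= 1")
  if (!is.finite(cfg$planted_log_or) || !is.finite(cfg$background_log_or))
    stop_cfg("log odds ratios must be finite")
  if (cfg$genome_length_per_chrom < 1)
    stop_cfg("'genome_length_per_chrom' must be positive")
  if (cfg$probes_per_kb <= 0)
    stop_cfg("'probes_per_kb' must be positive")
  if (cfg$cnv_length_log_sd <= 0)
    stop_cfg("'cnv_length_log_sd' must be positive")
  # median CNV length below the standard reliability filter would leave
  # almost nothing after filtering
  if (exp(cfg$cnv_length_log_mean) < 1e5)
    warning("configured median CNV length ", round(exp(cfg$cnv_length_log_mean)),
            " bp is below the 100 kb filter; the filtered cohort may be ",
            "nearly empty", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d on %d chromosomes (%.0f bp each)\n",
              x$n_genes, x$n_chroms, x$genome_length_per_chrom))
  cat(sprintf("  cohort: %d cases / %d controls, %d studies, %d chips\n",
              x$n_cases, x$n_controls, x$n_studies, x$n_chip_types))
  cat(sprintf("  CNVs: mean %.2f per subject, length ~ lognormal(%.2f, %.2f)\n",
              x$cnvs_per_subject_mean, x$cnv_length_log_mean,
              x$cnv_length_log_sd))
  cat(sprintf("  planted log OR: %.3f on %.0f%% of genes; background: %.3f\n",
              x$planted_log_or, 100 * x$planted_set_fraction,
              x$background_log_or))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
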