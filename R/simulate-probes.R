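#' Generate probe-level differential-expression p-values
#'
#' Emulates a two-normalization microarray analysis: every probe set carries
#' a pair of p-values (one per normalization channel). Null genes get two
#' independent Uniform(0,1) draws. Signal genes (a `signal_fraction` of the
#' universe, or an explicit `signal_genes` vector) get p-values derived from
#' one latent normal per probe shifted by `signal_effect`, with independent
#' channel noise added on top — so the two p-values of a signal probe are
#' both small and positively correlated, as dual normalizations of the same
#' hybridization are. A `frac_ambiguous_probes` fraction of probes targets
#' no unique gene (`source_gene_id` NA), to exercise probe filtering.
#'
#' @param genes gene annotation as from [gen_gene_annotation()].
#' @param config a [sim_config()].
#' @param signal_genes optional character vector of gene ids (in the human
#'   `HG` annotation space) forced to carry signal; overrides
#'   `config$signal_fraction` sampling.
#' @return A data.frame with columns `probe_id`, `source_gene_id` (the
#'   source-species `RG` gene the probe targets; NA for ambiguous probes),
#'   `p_mas5`, `p_rma`, with attribute `signal_genes` recording the
#'   ground-truth differentially expressed genes in human-id space.
#' @export
gen_probe_stats <- function(genes, config, signal_genes = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n_genes <- nrow(genes)
  if (is.null(signal_genes)) {
    n_sig <- round(config$signal_fraction * n_genes)
    signal_genes <- sort(sample(genes$gene_id, n_sig))
  } else {
    stopifnot(all(signal_genes %in% genes$gene_id))
    signal_genes <- sort(unique(signal_genes))
  }
  n_probes <- sample.int(config$probes_per_gene_max, n_genes, replace = TRUE)
  src <- rep(human_to_source(genes$gene_id), n_probes)
  is_sig <- src %in% human_to_source(signal_genes)
  m <- length(src)
  # latent per-probe effect shared between the two channels; null probes
  # have no shared component so their p-values are independent uniforms
  latent <- ifelse(is_sig, stats::rnorm(m, config$signal_effect, 1), 0)
  z1 <- latent + stats::rnorm(m, 0, 0.5)
  z2 <- latent + stats::rnorm(m, 0, 0.5)
  p1 <- ifelse(is_sig, stats::pnorm(z1, lower.tail = FALSE), stats::runif(m))
  p2 <- ifelse(is_sig, stats::pnorm(z2, lower.tail = FALSE), stats::runif(m))
  f <- config$frac_ambiguous_probes
  n_amb <- if (f > 0 && f < 1) round(f * m / (1 - f)) else if (f >= 1) m else 0L
  out <- data.frame(
    probe_id = sprintf("PR%06d", seq_len(m + n_amb)),
    source_gene_id = c(src, rep(NA_character_, n_amb)),
    p_mas5 = pmax(c(p1, stats::runif(n_amb)), 1e-300),
    p_rma = pmax(c(p2, stats::runif(n_amb)), 1e-300),
    stringsAsFactors = FALSE
  )
  attr(out, "signal_genes") <- signal_genes
  out
}
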