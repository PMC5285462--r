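#' Generate a non-overlapping gene annotation
#'
#' Lays out `n_genes` genes over `n_chroms` chromosomes, as evenly as the
#' division allows, each gene a non-overlapping interval in 1-based inclusive
#' coordinates. Gene lengths are lognormal around 20 kb, capped so each gene
#' fits inside its own slot, which guarantees the non-overlap invariant by
#' construction.
#'
#' The annotation plays the role of the human genome build CNVs are
#' annotated against; identifiers are `HG#####`. Source-species (expression
#' experiment) genes are generated by [gen_homology_table()] as `RG#####`,
#' paired to human genes by index.
#'
#' @param config a [sim_config()].
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), sorted by chromosome then start.
#' @export
gen_gene_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1L)))
  L <- config$genome_length_per_chrom
  if (any(per_chrom > 0 & floor(L / pmax(per_chrom, 1L)) < 1000))
    stop("genome too small to place ", config$n_genes, " genes on ",
         config$n_chroms, " chromosomes of ", L, " bp", call. = FALSE)
  out <- vector("list", config$n_chroms)
  gi <- 0L
  for (ch in seq_len(config$n_chroms)) {
    k <- per_chrom[ch]
    if (k == 0L) next
    slot <- floor(L / k)
    len <- pmin(pmax(round(stats::rlnorm(k, log(2e4), 0.6)), 100L), slot - 2L)
    start0 <- floor(stats::runif(k, 0, slot - len)) # offset within slot, 0-based
    start <- (seq_len(k) - 1L) * slot + start0 + 1L
    out[[ch]] <- data.frame(
      gene_id = sprintf("HG%05d", gi + seq_len(k)),
      chrom = sprintf("chr%d", ch),
      start = start,
      end = start + len - 1L,
      stringsAsFactors = FALSE
    )
    gi <- gi + k
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann
}

# the source-species gene paired (by index) with a human gene, and back
human_to_source <- function(human_ids) sub("^HG", "RG", human_ids)
source_to_human <- function(source_ids) sub("^RG", "HG", source_ids)

#' Generate a synthetic homology table
#'
#' Emulates a HomoloGene-style cross-species mapping between source-species
#' genes (`RG#####`, the genes probes target) and the human annotation
#' universe (`HG#####`). Each source gene is either unmapped (absent from
#' the table), mapped to exactly one human gene (its index-paired partner),
#' or mapped to more than one human gene, in the configured expected
#' proportions. Each homology group carries a shared `group_id`.
#' Multimapped source genes pick up a second, random human gene, which also
#' exercises the human-side uniqueness rule downstream (that human gene now
#' receives two source genes).
#'
#' @param genes gene annotation as from [gen_gene_annotation()].
#' @param frac_unmapped expected fraction of source genes with no human
#'   homolog.
#' @param frac_multimapped expected fraction of source genes mapping to two
#'   human genes.
#' @param seed integer seed.
#' @return A data.frame with columns `group_id`, `source_gene_id`,
#'   `human_gene_id`; unmapped source genes do not appear.
#' @export
gen_homology_table <- function(genes, frac_unmapped = 0.1,
                               frac_multimapped = 0.05, seed = 1L) {
  if (frac_unmapped + frac_multimapped > 1)
    stop("frac_unmapped + frac_multimapped must be <= 1", call. = FALSE)
  set.seed(seed)
  human <- genes$gene_id
  source <- human_to_source(human)
  n <- length(human)
  status <- sample(c("unmapped", "multi", "unique"), n, replace = TRUE,
                   prob = c(frac_unmapped, frac_multimapped,
                            1 - frac_unmapped - frac_multimapped))
  group <- sprintf("GRP%05d", seq_len(n))
  keep <- status != "unmapped"
  rows <- data.frame(group_id = group[keep],
                     source_gene_id = source[keep],
                     human_gene_id = human[keep],
                     stringsAsFactors = FALSE)
  multi <- which(status == "multi")
  if (length(multi) > 0 && n > 1) {
    extra_hum <- vapply(multi, function(i)
      sample(human[-i], 1L), character(1))
    rows <- rbind(rows, data.frame(group_id = group[multi],
                                   source_gene_id = source[multi],
                                   human_gene_id = extra_hum,
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$group_id, rows$human_gene_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
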