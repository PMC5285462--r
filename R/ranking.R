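#' Remove probes without a unique gene target
#'
#' @param probes probe data.frame (`probe_id`, `source_gene_id`, `p_mas5`,
#'   `p_rma`); probes with missing/empty `source_gene_id` are dropped.
#' @return The retained probes; the number removed is attached as attribute
#'   `n_removed` and reported via message.
#' @export
filter_probes <- function(probes) {
  if (nrow(probes) == 0) {
    warning("empty probe table", call. = FALSE)
    attr(probes, "n_removed") <- 0L
    return(probes)
  }
  bad <- is.na(probes$source_gene_id) | probes$source_gene_id == ""
  out <- probes[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(bad)
  if (sum(bad) > 0)
    message("filter_probes: removed ", sum(bad),
            " probe(s) without a unique gene target")
  if (nrow(out) == 0)
    warning("no probes left after filtering", call. = FALSE)
  out
}

# floor applied to p-values before log transforms; guards against underflow
.P_FLOOR <- 1e-300

#' Combine two p-values with Fisher's method
#'
#' For a pair of p-values the Fisher statistic is
#' \eqn{X = -2(\ln p_1 + \ln p_2)}, referred to a chi-square distribution
#' with 4 degrees of freedom; the combined p-value is the upper tail
#' probability at X. Vectorized over pairs.
#'
#' @param p1,p2 p-values in (0, 1]. Values below `1e-300` are clamped to
#'   that floor (with a warning) before taking logs.
#' @return Combined p-values in (0, 1].
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 > 1 | p2 > 1, na.rm = TRUE) || any(is.na(p1) | is.na(p2)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (any(p1 <= 0 | p2 <= 0))
    stop("p-values must be strictly positive", call. = FALSE)
  if (any(p1 < .P_FLOOR | p2 < .P_FLOOR)) {
    warning("p-values below 1e-300 clamped before log transform",
            call. = FALSE)
    p1 <- pmax(p1, .P_FLOOR)
    p2 <- pmax(p2, .P_FLOOR)
  }
  x <- -2 * (log(p1) + log(p2))
  stats::pchisq(x, df = 4, lower.tail = FALSE)
}

#' Combine p-values with the Simes procedure
#'
#' With order statistics \eqn{p_{(1)} \le \dots \le p_{(m)}}, returns
#' \eqn{\min_i m \, p_{(i)} / i}, capped at 1. Valid under independence or
#' positive dependence of the component tests; used here to collapse the
#' Fisher-combined p-values of a gene's multiple probe sets to one p-value
#' per gene.
#'
#' @param pvals non-empty numeric vector of p-values in (0, 1].
#' @return A single combined p-value.
#' @export
simes_combine <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value list", call. = FALSE)
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(pvals)
  min(1, min(m * sort(pvals) / seq_len(m)))
}

#' Collapse probe-level p-values to a ranked human gene list
#'
#' Per probe, the two normalization p-values are Fisher-combined; per source
#' gene, the probe-level combined p-values are Simes-collapsed to one
#' p-value. Source genes are then mapped to human identifiers through the
#' homology table; genes that are unmapped, map to more than one human gene,
#' or share a human gene with another source gene are excluded (uniqueness
#' enforced in both directions by default). The result is ranked by combined
#' p-value, ties broken by gene identifier.
#'
#' @param probes filtered probe data.frame (see [filter_probes()]).
#' @param homology homology table (`group_id`, `source_gene_id`,
#'   `human_gene_id`).
#' @param bidirectional if TRUE (default), a human gene receiving more than
#'   one source gene is also excluded; if FALSE only source-to-human
#'   uniqueness is required.
#' @return data.frame (`human_gene_id`, `source_gene_id`, `combined_p`,
#'   `rank`), sorted so rank 1 is most significant; exclusion counts are
#'   attached as attribute `excluded`.
#' @export
collapse_to_genes <- function(probes, homology, bidirectional = TRUE) {
  dt <- data.table::as.data.table(probes)
  dt <- dt[!is.na(source_gene_id) & source_gene_id != ""]
  if (nrow(dt) == 0) {
    warning("no probes with gene targets; empty ranking", call. = FALSE)
    return(data.frame(human_gene_id = character(0),
                      source_gene_id = character(0),
                      combined_p = numeric(0), rank = integer(0)))
  }
  dt[, fisher_p := fisher_combine(p_mas5, p_rma)]
  per_gene <- dt[, .(combined_p = simes_combine(fisher_p)),
                 by = source_gene_id]

  hom <- data.table::as.data.table(homology)
  n_human_per_src <- hom[, .(n_h = data.table::uniqueN(human_gene_id)),
                         by = source_gene_id]
  multi_src <- n_human_per_src[n_h > 1, source_gene_id]
  hom1 <- hom[!source_gene_id %in% multi_src]
  if (bidirectional) {
    n_src_per_hum <- hom1[, .(n_s = data.table::uniqueN(source_gene_id)),
                          by = human_gene_id]
    shared_hum <- n_src_per_hum[n_s > 1, human_gene_id]
    hom1 <- hom1[!human_gene_id %in% shared_hum]
  }
  merged <- merge(per_gene, unique(hom1[, .(source_gene_id, human_gene_id)]),
                  by = "source_gene_id")
  n_unmapped <- sum(!per_gene$source_gene_id %in% hom$source_gene_id)
  n_multi <- sum(per_gene$source_gene_id %in% multi_src)
  excluded <- c(
    unmapped = n_unmapped,
    multimapped = n_multi,
    shared_human = nrow(per_gene) - n_unmapped - n_multi - nrow(merged)
  )
  if (nrow(merged) == 0) {
    warning("no genes with a unique human homolog; empty ranking",
            call. = FALSE)
    out <- data.frame(human_gene_id = character(0),
                      source_gene_id = character(0),
                      combined_p = numeric(0), rank = integer(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  data.table::setorder(merged, combined_p, human_gene_id)
  out <- data.frame(human_gene_id = merged$human_gene_id,
                    source_gene_id = merged$source_gene_id,
                    combined_p = merged$combined_p,
                    rank = seq_len(nrow(merged)),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Select the top fraction of a gene ranking as a gene set
#'
#' Takes the `floor(fraction * N)` most significant genes. Ties at the
#' cutoff are resolved deterministically because the ranking is sorted by
#' (combined_p, gene id).
#'
#' @param scores ranked gene table from [collapse_to_genes()].
#' @param fraction selection fraction in (0, 1].
#' @param label set label (e.g. the learning condition the ranking came
#'   from).
#' @return An object of class `gene_set`: list(label, fraction, members).
#' @export
select_top_fraction <- function(scores, fraction, label = "gene_set") {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  n <- floor(fraction * nrow(scores))
  if (n < 1)
    stop("fraction ", fraction, " of ", nrow(scores),
         " genes selects an empty set", call. = FALSE)
  ord <- order(scores$combined_p, scores$human_gene_id)
  structure(list(label = label, fraction = fraction,
                 members = scores$human_gene_id[ord][seq_len(n)]),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s'> fraction %g, %d members\n",
              x$label, x$fraction, length(x$members)))
  invisible(x)
}

#' Rank one probe table end to end and write outputs
#'
#' Composition of [filter_probes()], [collapse_to_genes()] and
#' [select_top_fraction()] with file output: writes the ranked gene TSV and
#' one gene-set file per requested fraction.
#'
#' @param probe_path probe TSV path.
#' @param homology_path homology TSV path.
#' @param out_dir output directory.
#' @param label condition label used in output names.
#' @param fractions selection fractions.
#' @return Invisibly, list(ranking, sets, paths).
#' @export
run_rank <- function(probe_path, homology_path, out_dir, label,
                     fractions = c(0.01, 0.02, 0.05, 0.10, 0.15, 0.20, 0.25)) {
  probes <- read_probe_table(probe_path)
  homology <- read_homology_table(homology_path)
  if (nrow(homology) == 0)
    stop("empty homology table: no genes can be mapped", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probes <- filter_probes(probes)
  ranking <- collapse_to_genes(probes, homology)
  rank_path <- file.path(out_dir, sprintf("ranking_%s.tsv", label))
  write_result_table(ranking[, c("human_gene_id", "combined_p", "rank")],
                     rank_path, list(label = label))
  archive_run_config(list(probe_path = probe_path,
                          homology_path = homology_path, label = label,
                          fractions = fractions),
                     out_dir, sprintf("rank_config_%s.json", label))
  sets <- list()
  paths <- list(ranking = rank_path)
  for (f in fractions) {
    gs <- select_top_fraction(ranking, f, label = label)
    p <- file.path(out_dir, sprintf("geneset_%s_top%g.txt", label, 100 * f))
    write_gene_set(gs, p)
    sets[[as.character(f)]] <- gs
    paths[[sprintf("set_%g", f)]] <- p
  }
  invisible(list(ranking = ranking, sets = sets, paths = paths))
}
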