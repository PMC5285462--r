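utils::globalVariables(c("source_gene_id", "fisher_p", "n_h", "n_s",
                         "human_gene_id", "fraction", "signed_log_stat",
                         "set_label"))

# write a TSV with a leading comment line naming the package version and the
# resolved run parameters; readers skip it (comment.char = "#") and repeated
# runs stay byte-identical because the line carries no timestamp
write_result_table <- function(df, path, params = list()) {
  ver <- as.character(utils::packageVersion("cnvburden"))
  meta <- if (length(params) > 0)
    paste(names(params), vapply(params, function(x)
      paste(format(x, trim = TRUE), collapse = ","), character(1)),
      sep = "=", collapse = " ")
  else ""
  writeLines(trimws(sprintf("# cnvburden %s %s", ver, meta)), path)
  suppressWarnings(
    utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                       sep = "\t", append = TRUE))
  invisible(path)
}

# archive the resolved configuration of a run beside its outputs; the JSON
# round-trips through jsonlite so a run can be reproduced from its archive
archive_run_config <- function(params, out_dir, name) {
  path <- file.path(out_dir, name)
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the enrichment stage end to end from files
#'
#' Reads the CNV file, subject table, gene annotation and gene-set files;
#' applies the reliability filter; annotates CNVs with overlapping genes;
#' fits the covariate-adjusted burden regression for every gene set in every
#' requested stratum (with Bonferroni correction over the gene-set family);
#' optionally computes the permutation-corrected threshold profile; and
#' writes the result tables.
#'
#' @param cnv_path .cnv file path.
#' @param subject_path subject TSV path.
#' @param gene_bed_path gene annotation BED path.
#' @param gene_set_paths character vector of gene-set file paths (as written
#'   by [write_gene_set()]).
#' @param out_dir output directory.
#' @param strata which CNV strata to analyze.
#' @param min_length,min_probes reliability filter thresholds.
#' @param ranking_paths optional named character vector of ranked-gene TSV
#'   paths (one per condition); when given together with `n_perm > 0`, the
#'   permutation threshold profile is computed across `fractions`.
#' @param fractions selection fractions for the profile.
#' @param n_perm number of permutations (0 disables the profile and the
#'   empirical columns).
#' @param per_gene if TRUE, also writes the per-gene contribution table for
#'   each gene set (all-CNV stratum).
#' @param seed seed for the permutation stream.
#' @return Invisibly, list(enrichment, profile, per_gene, paths).
#' @export
run_enrich <- function(cnv_path, subject_path, gene_bed_path, gene_set_paths,
                       out_dir,
                       strata = c("all", "deletion", "duplication"),
                       min_length = 1e5, min_probes = 15L,
                       ranking_paths = NULL,
                       fractions = c(0.01, 0.02, 0.05, 0.10, 0.15, 0.20, 0.25),
                       n_perm = 0L,
                       per_gene = FALSE,
                       seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cnvs <- read_cnv_file(cnv_path)
  subjects <- read_subject_table(subject_path)
  genes <- read_gene_bed(gene_bed_path)
  gene_sets <- lapply(gene_set_paths, read_gene_set)

  flt <- filter_cnvs(cnvs, min_length, min_probes)
  ann <- annotate_cnvs(flt, genes)

  m <- length(gene_sets)
  enr <- list()
  for (st in strata) {
    ann_st <- stratify_by_type(ann, st)
    for (gs in gene_sets) {
      burden <- build_burden_table(subjects, ann_st, gs, stratum = "all")
      enr[[length(enr) + 1L]] <-
        fit_enrichment(burden, set_label = gs$label, stratum = st,
                       m_bonferroni = m)
    }
  }
  enrichment <- do.call(rbind, enr)
  run_params <- list(cnv_path = cnv_path, subject_path = subject_path,
                     gene_bed_path = gene_bed_path,
                     gene_sets = vapply(gene_sets, `[[`, "", "label"),
                     strata = strata, min_length = min_length,
                     min_probes = min_probes, fractions = fractions,
                     n_perm = n_perm, seed = seed)
  paths <- list(enrichment = file.path(out_dir, "enrichment.tsv"),
                config = archive_run_config(run_params, out_dir,
                                            "enrich_config.json"))
  write_result_table(enrichment, paths$enrichment,
                     list(min_length = min_length, min_probes = min_probes,
                          m_bonferroni = m))

  profile <- NULL
  if (!is.null(ranking_paths) && n_perm > 0) {
    rankings <- lapply(ranking_paths, function(p) {
      rk <- utils::read.table(p, header = TRUE, stringsAsFactors = FALSE,
                              sep = "\t")
      rk[order(rk$rank), , drop = FALSE]
    })
    if (is.null(names(rankings)))
      names(rankings) <- sprintf("condition%d", seq_along(rankings))
    profile <- threshold_profile(rankings, ann, subjects,
                                 fractions = fractions, n_perm = n_perm,
                                 seed = seed)
    paths$profile <- file.path(out_dir, "threshold_profile.tsv")
    write_result_table(profile, paths$profile,
                       list(n_perm = n_perm, seed = seed))
  }

  per_gene_tab <- NULL
  if (per_gene) {
    pg <- lapply(gene_sets, function(gs) {
      tab <- per_gene_enrichment(subjects, ann, gs)
      cbind(set_label = gs$label, tab, stringsAsFactors = FALSE)
    })
    per_gene_tab <- do.call(rbind, pg)
    paths$per_gene <- file.path(out_dir, "per_gene.tsv")
    write_result_table(per_gene_tab, paths$per_gene,
                       list(min_length = min_length,
                            min_probes = min_probes))
  }
  invisible(list(enrichment = enrichment, profile = profile,
                 per_gene = per_gene_tab, paths = paths))
}
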