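#' Build the per-subject burden table
#'
#' Aggregates a subject's (filtered, stratum-restricted, gene-annotated)
#' CNVs into the regression's unit of analysis: phenotype, count of distinct
#' gene-set genes hit, total CNV kb, total distinct genes hit, chip and
#' study. Subjects without CNVs are retained with zero burden — they carry
#' baseline information, and dropping them would condition on CNV carriage.
#'
#' @param subjects subject data.frame (`subject_id`, `phenotype`, `chip`,
#'   `study`).
#' @param annotated annotated CNVs from [annotate_cnvs()] (already filtered).
#' @param gene_set a `gene_set` object or character vector of member ids.
#' @param stratum one of "all", "deletion", "duplication"; restricts the
#'   CNVs before aggregation.
#' @param strict if TRUE (default), a CNV subject absent from the subject
#'   table is an error naming the subject; if FALSE such CNVs are dropped
#'   with a warning.
#' @return data.frame with one row per subject: `subject_id`, `phenotype`,
#'   `set_hits`, `total_cnv_kb`, `total_genes_hit`, `chip`, `study`.
#' @export
build_burden_table <- function(subjects, annotated, gene_set,
                               stratum = c("all", "deletion", "duplication"),
                               strict = TRUE) {
  stratum <- match.arg(stratum)
  members <- if (inherits(gene_set, "gene_set")) gene_set$members else gene_set
  if (length(members) == 0) stop("empty gene set", call. = FALSE)
  cn <- stratify_by_type(annotated, stratum)
  unknown <- setdiff(unique(cn$subject_id), subjects$subject_id)
  if (length(unknown) > 0) {
    msg <- paste0("CNV subject(s) absent from subject table: ",
                  paste(utils::head(unknown, 5), collapse = ", "),
                  if (length(unknown) > 5) ", ...")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropping their CNVs", call. = FALSE)
    cn <- cn[cn$subject_id %in% subjects$subject_id, , drop = FALSE]
  }
  sid_levels <- subjects$subject_id
  kb <- tapply(cn$length / 1000, factor(cn$subject_id, levels = sid_levels),
               sum, default = 0)
  pairs <- if (nrow(cn) > 0) unique(cnv_gene_pairs(cn)[, c("subject_id", "gene_id")])
           else data.frame(subject_id = character(0), gene_id = character(0))
  sid <- factor(pairs$subject_id, levels = sid_levels)
  total_hits <- as.integer(table(sid))
  set_hits <- as.integer(table(sid[pairs$gene_id %in% members]))
  data.frame(
    subject_id = subjects$subject_id,
    phenotype = subjects$phenotype,
    set_hits = set_hits,
    total_cnv_kb = as.numeric(kb),
    total_genes_hit = total_hits,
    chip = subjects$chip,
    study = subjects$study,
    stringsAsFactors = FALSE
  )
}

#' Fit the covariate-adjusted burden logistic regression
#'
#' Maximum-likelihood logistic regression of case-control status on the
#' gene-set hit count, adjusting for total CNV size (kb), total number of
#' genes hit, chip type and study (dummy-coded). The reported test is the
#' two-tailed Wald test on the `set_hits` coefficient. Single-level
#' categorical covariates are dropped automatically; constant `set_hits` and
#' (quasi-)separation are flagged rather than returned as silent NaNs.
#'
#' @param burden burden table from [build_burden_table()].
#' @param covariates character vector of covariate columns to adjust for;
#'   default is the full set. An empty vector fits the crude model.
#' @param set_label,stratum labels carried into the result row.
#' @param m_bonferroni family size for Bonferroni correction (default 3, one
#'   test per learning-condition gene set).
#' @return One-row data.frame of class `enrichment_result`: `set_label`,
#'   `stratum`, `beta`, `se`, `z`, `p`, `p_corrected`, `n_case`,
#'   `n_control`, `flag` ("" when clean).
#' @export
fit_enrichment <- function(burden,
                           covariates = c("total_cnv_kb", "total_genes_hit",
                                          "chip", "study"),
                           set_label = "gene_set",
                           stratum = "all",
                           m_bonferroni = 3L) {
  n_case <- sum(burden$phenotype == 1L)
  n_control <- sum(burden$phenotype == 0L)
  res <- function(beta, se, z, p, flag) {
    out <- data.frame(set_label = set_label, stratum = stratum,
                      beta = beta, se = se, z = z, p = p,
                      p_corrected = if (is.na(p)) NA_real_ else bonferroni(p, m_bonferroni),
                      n_case = n_case, n_control = n_control,
                      flag = flag, stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    out
  }
  if (n_case == 0 || n_control == 0)
    return(res(NA_real_, NA_real_, NA_real_, NA_real_, "single_class_outcome"))
  if (length(unique(burden$set_hits)) == 1L)
    return(res(NA_real_, NA_real_, NA_real_, NA_real_, "constant_predictor"))
  keep_cov <- covariates[vapply(covariates, function(v)
    length(unique(burden[[v]])) > 1L, logical(1))]
  dropped <- setdiff(covariates, keep_cov)
  if (length(dropped) > 0)
    message("fit_enrichment: dropping single-level covariate(s): ",
            paste(dropped, collapse = ", "))
  fml <- stats::reformulate(c("set_hits", keep_cov), response = "phenotype")
  dat <- burden
  for (v in intersect(keep_cov, c("chip", "study")))
    dat[[v]] <- factor(dat[[v]])
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  if (!"set_hits" %in% rownames(co) || is.na(co["set_hits", 1]))
    return(res(NA_real_, NA_real_, NA_real_, NA_real_, "non_estimable"))
  beta <- co["set_hits", 1]
  se <- co["set_hits", 2]
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  flag <- ""
  mu <- fit$fitted.values
  if (!fit$converged) flag <- "not_converged"
  else if (abs(beta) > 15 || se > 100 || any(mu < 1e-10) || any(mu > 1 - 1e-10))
    flag <- "separation"
  res(beta, se, z, p, flag)
}

#' Bonferroni correction
#'
#' @param p p-value(s).
#' @param m number of tests in the family (>= 1).
#' @return `min(1, m * p)`, vectorized.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  pmin(1, m * p)
}

#' Per-gene contribution to a gene set's enrichment
#'
#' Refits the burden regression once per gene-set member, replacing the
#' set-level hit count with that single gene's 0/1 hit indicator. Reported
#' p-values are uncorrected: this is an exploratory decomposition of the
#' set-level signal, not a family of confirmatory tests. Genes hit by no
#' subject are reported with flag "constant_predictor".
#'
#' @param subjects,annotated,gene_set,stratum,covariates as in
#'   [build_burden_table()] / [fit_enrichment()].
#' @return data.frame with one row per set member: `gene_id`, `n_carriers`,
#'   `n_case_carriers`, `beta`, `se`, `z`, `p`, `flag`.
#' @export
per_gene_enrichment <- function(subjects, annotated, gene_set,
                                stratum = "all",
                                covariates = c("total_cnv_kb",
                                               "total_genes_hit",
                                               "chip", "study")) {
  members <- if (inherits(gene_set, "gene_set")) gene_set$members else gene_set
  burden <- build_burden_table(subjects, annotated, members, stratum)
  cn <- stratify_by_type(annotated, stratum)
  pairs <- if (nrow(cn) > 0) unique(cnv_gene_pairs(cn)[, c("subject_id", "gene_id")])
           else data.frame(subject_id = character(0), gene_id = character(0))
  rows <- lapply(members, function(g) {
    carriers <- unique(pairs$subject_id[pairs$gene_id == g])
    b <- burden
    b$set_hits <- as.integer(b$subject_id %in% carriers)
    r <- suppressMessages(fit_enrichment(b, covariates, set_label = g,
                                         stratum = stratum, m_bonferroni = 1L))
    data.frame(gene_id = g,
               n_carriers = length(carriers),
               n_case_carriers = sum(burden$phenotype[burden$subject_id %in%
                                                        carriers] == 1L),
               beta = r$beta, se = r$se, z = r$z, p = r$p, flag = r$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
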