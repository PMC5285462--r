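#' Generate a case-control CNV cohort with a planted gene-set effect
#'
#' Subjects receive Poisson-many CNV calls with lognormal lengths, probe
#' counts proportional to length, and deletion/duplication types. Phenotype
#' is then generated *conditionally on CNV burden* through a logistic model
#' whose linear predictor contains `planted_log_or` times the number of
#' distinct planted-set genes overlapped by the subject's filter-passing
#' CNVs (plus optionally `background_log_or` times the total distinct genes
#' hit). The intercept is solved numerically so the realized case fraction
#' matches `n_cases / (n_cases + n_controls)`. This makes the planted
#' log odds ratio the literal estimand of the downstream burden regression.
#'
#' Burden is counted on calls passing the standard >= 100 kb / >= 15 probe
#' filter, i.e. on the calls the downstream analysis actually sees. If
#' `size_confounding_factor > 1`, case CNV lengths are scaled up *after*
#' phenotype assignment (extending the interval end, recomputing probe
#' counts), inducing the case-control size confound the covariates must
#' absorb.
#'
#' @param genes gene annotation from [gen_gene_annotation()].
#' @param gene_set_truth character vector of planted causal gene ids (may be
#'   empty only when `planted_log_or == 0`).
#' @param config a [sim_config()].
#' @return list with elements `subjects` (subject_id, phenotype, chip,
#'   study), `cnvs` (CNV data.frame), and `truth` (planted set, log OR,
#'   solved intercept, per-subject planted hit counts).
#' @export
gen_cnv_cohort <- function(genes, gene_set_truth, config) {
  validate_sim_config(config)
  if (length(gene_set_truth) == 0 && config$planted_log_or != 0)
    stop("planted gene set is empty but planted_log_or != 0", call. = FALSE)
  if (!all(gene_set_truth %in% genes$gene_id))
    stop("gene_set_truth contains ids outside the gene universe",
         call. = FALSE)
  set.seed(config$seed + 2L)
  n <- config$n_cases + config$n_controls
  subj_id <- sprintf("S%05d", seq_len(n))
  study <- sprintf("study%d", sample.int(config$n_studies, n, replace = TRUE))
  chip <- sprintf("chip%d", sample.int(config$n_chip_types, n, replace = TRUE))

  n_cnv <- stats::rpois(n, config$cnvs_per_subject_mean)
  m <- sum(n_cnv)
  cnvs <- if (m == 0) {
    data.frame(subject_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), type = character(0),
               n_probes = integer(0), length = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    L <- config$genome_length_per_chrom
    len <- pmin(pmax(round(stats::rlnorm(m, config$cnv_length_log_mean,
                                         config$cnv_length_log_sd)), 1), L)
    start <- floor(stats::runif(m, 0, L - len)) + 1
    data.frame(
      subject_id = rep(subj_id, n_cnv),
      chrom = sprintf("chr%d", sample.int(config$n_chroms, m, replace = TRUE)),
      start = start,
      end = start + len - 1,
      type = ifelse(stats::runif(m) < config$deletion_fraction,
                    "deletion", "duplication"),
      n_probes = pmax(1L, as.integer(round(config$probes_per_kb * len / 1000))),
      length = len,
      stringsAsFactors = FALSE
    )
  }

  # burden as the downstream analysis will measure it: filter, then count
  # distinct planted-set genes (and all genes) per subject
  flt <- filter_cnvs(cnvs, quiet = TRUE)
  hits <- subject_hit_counts(flt, genes, subj_id)
  planted_hits <- hits$count_in(gene_set_truth)
  total_hits <- hits$total

  case_frac <- config$n_cases / n
  eta <- config$planted_log_or * planted_hits +
    config$background_log_or * total_hits
  alpha <- solve_intercept(eta, case_frac)
  phenotype <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))

  if (config$size_confounding_factor > 1 && nrow(cnvs) > 0) {
    case_ids <- subj_id[phenotype == 1L]
    idx <- cnvs$subject_id %in% case_ids
    newlen <- pmin(round(cnvs$length[idx] * config$size_confounding_factor),
                   config$genome_length_per_chrom - cnvs$start[idx] + 1)
    cnvs$length[idx] <- newlen
    cnvs$end[idx] <- cnvs$start[idx] + newlen - 1
    cnvs$n_probes[idx] <- pmax(1L, as.integer(round(config$probes_per_kb *
                                                      newlen / 1000)))
  }

  list(
    subjects = data.frame(subject_id = subj_id, phenotype = phenotype,
                          chip = chip, study = study,
                          stringsAsFactors = FALSE),
    cnvs = cnvs,
    truth = list(planted_set = gene_set_truth,
                 planted_log_or = config$planted_log_or,
                 background_log_or = config$background_log_or,
                 intercept = alpha,
                 planted_hits = stats::setNames(planted_hits, subj_id))
  )
}

# per-subject distinct-gene hit counts; returns the total count and a
# closure counting hits restricted to an arbitrary gene subset
subject_hit_counts <- function(cnvs, genes, subject_ids) {
  if (nrow(cnvs) == 0) {
    zero <- stats::setNames(integer(length(subject_ids)), subject_ids)
    return(list(total = zero, count_in = function(set) zero))
  }
  ann <- annotate_cnvs(cnvs, genes)
  pairs <- cnv_gene_pairs(ann)
  pairs <- unique(pairs[, c("subject_id", "gene_id")])
  sid <- factor(pairs$subject_id, levels = subject_ids)
  total <- as.integer(table(sid))
  names(total) <- subject_ids
  list(
    total = total,
    count_in = function(set) {
      keep <- pairs$gene_id %in% set
      cnt <- as.integer(table(sid[keep]))
      stats::setNames(cnt, subject_ids)
    }
  )
}

# solve the logistic intercept so the expected case fraction matches the
# target; handles the degenerate all-zero-burden cohort exactly
solve_intercept <- function(eta, case_frac) {
  f <- function(a) mean(stats::plogis(a + eta)) - case_frac
  if (all(eta == eta[1])) return(stats::qlogis(case_frac) - eta[1])
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Write all synthetic-data outputs for one simulated study
#'
#' Drives the full generator and serializes every artifact: gene BED,
#' homology TSV, one probe TSV per condition, CNV file, subject TSV, and a
#' ground-truth JSON (planted set, signal genes per condition, planted log
#' odds ratio).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param conditions labels of the expression conditions to simulate. The
#'   first condition's differentially expressed genes are the planted causal
#'   CNV set; the remaining conditions carry signal unrelated to phenotype.
#' @param frac_unmapped,frac_multimapped homology-table proportions.
#' @return Invisibly, a named list of the generated objects and file paths.
#' @export
run_simulate <- function(config, out_dir,
                         conditions = c("extinction", "consolidation",
                                        "retrieval"),
                         frac_unmapped = 0.1, frac_multimapped = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- gen_gene_annotation(config)
  homology <- gen_homology_table(genes, frac_unmapped, frac_multimapped,
                                 seed = config$seed)
  set.seed(config$seed + 3L)
  planted <- sort(sample(genes$gene_id,
                         round(config$planted_set_fraction * nrow(genes))))
  # conditions regulate essentially distinct gene groups: the first
  # condition's signal genes are the planted causal set, and each further
  # condition draws its signal genes disjointly from the remaining genes
  probes <- list()
  signal_genes <- list()
  used <- planted
  for (i in seq_along(conditions)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + 10L * i
    sig <- if (i == 1L) planted else {
      set.seed(config$seed + 4L + i)
      pool <- setdiff(genes$gene_id, used)
      sort(sample(pool, min(length(pool),
                            round(config$signal_fraction * nrow(genes)))))
    }
    used <- union(used, sig)
    ps <- gen_probe_stats(genes, cfg_i, signal_genes = sig)
    probes[[conditions[i]]] <- ps
    signal_genes[[conditions[i]]] <- sig
  }
  cohort <- gen_cnv_cohort(genes, planted, config)

  paths <- list(
    genes = file.path(out_dir, "genes.bed"),
    homology = file.path(out_dir, "homology.tsv"),
    cnv = file.path(out_dir, "cohort.cnv"),
    subjects = file.path(out_dir, "subjects.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_gene_bed(genes, paths$genes)
  write_homology_table(homology, paths$homology)
  write_cnv_file(cohort$cnvs, paths$cnv)
  write_subject_table(cohort$subjects, paths$subjects)
  for (cond in conditions) {
    p <- file.path(out_dir, sprintf("probes_%s.tsv", cond))
    write_probe_table(probes[[cond]], p)
    paths[[paste0("probes_", cond)]] <- p
  }
  paths$config <- archive_run_config(
    c(unclass(config), list(conditions = conditions,
                            frac_unmapped = frac_unmapped,
                            frac_multimapped = frac_multimapped)),
    out_dir, "simulate_config.json")
  jsonlite::write_json(
    list(planted_set = planted,
         planted_log_or = config$planted_log_or,
         signal_genes = signal_genes,
         seed = config$seed),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genes = genes, homology = homology, probes = probes,
                 cohort = cohort, planted = planted, paths = paths))
}
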