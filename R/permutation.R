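#' Sparse subject-by-gene hit matrix
#'
#' Binary incidence of distinct gene hits per subject, computed once from
#' the annotated CNVs and then reused for every observed and permuted gene
#' set: a set's per-subject hit count is a row sum over the member columns,
#' so permutation never re-annotates CNVs.
#'
#' @param subjects subject data.frame.
#' @param annotated annotated (filtered, stratified) CNVs.
#' @param universe character vector of gene ids defining the columns
#'   (typically the ranking universe).
#' @return A sparse logical Matrix, rows = subjects (named), columns =
#'   universe genes (named).
#' @export
subject_gene_matrix <- function(subjects, annotated, universe) {
  pairs <- if (nrow(annotated) > 0)
    unique(cnv_gene_pairs(annotated)[, c("subject_id", "gene_id")])
  else data.frame(subject_id = character(0), gene_id = character(0))
  pairs <- pairs[pairs$gene_id %in% universe, , drop = FALSE]
  i <- match(pairs$subject_id, subjects$subject_id)
  j <- match(pairs$gene_id, universe)
  ok <- !is.na(i)
  Matrix::sparseMatrix(i = i[ok], j = j[ok],
                       dims = c(nrow(subjects), length(universe)),
                       dimnames = list(subjects$subject_id, universe))
}

#' Generate permuted top-fraction gene sets
#'
#' Each permutation shuffles the whole gene universe once and takes its top
#' fractions, so within one permutation the smaller sets are nested in the
#' larger ones — a single-shuffle construction matching how the observed
#' nested top-fraction sets arise from one ranking.
#'
#' @param universe character vector of gene ids (the ranking universe).
#' @param fractions selection fractions.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list of length `n_perm`; each element is a named list of member
#'   vectors, one per fraction.
#' @export
permute_gene_sets <- function(universe, fractions, n_perm, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  sizes <- floor(fractions * length(universe))
  if (any(sizes < 1))
    stop("some fraction selects an empty set from a universe of ",
         length(universe), call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_perm), function(i) {
    shuffled <- sample(universe)
    stats::setNames(lapply(sizes, function(k) shuffled[seq_len(k)]),
                    as.character(fractions))
  })
}

#' Permutation empirical p-value
#'
#' Fraction of null statistics as or more significant than the observed one;
#' ties count as "as significant". The default plain-fraction estimator can
#' return exactly 0; `mode = "add_one"` uses the (k+1)/(N+1) estimator.
#'
#' @param observed_p observed (asymptotic) p-value.
#' @param null_ps non-empty vector of null p-values from permuted sets.
#' @param mode "plain" (default) or "add_one".
#' @return Empirical p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(observed_p, null_ps, mode = c("plain", "add_one")) {
  mode <- match.arg(mode)
  null_ps <- null_ps[!is.na(null_ps)]
  if (length(null_ps) == 0) stop("empty null distribution", call. = FALSE)
  k <- sum(null_ps <= observed_p)
  if (mode == "plain") k / length(null_ps)
  else (k + 1) / (length(null_ps) + 1)
}

# logistic fit on a precomputed covariate design; returns the Wald z and
# two-tailed p of the hit-count column only. Used for the thousands of
# permuted refits where only set_hits changes.
fast_burden_fit <- function(y, X_cov, hits) {
  if (length(unique(hits)) == 1L) return(c(z = NA_real_, p = NA_real_))
  X <- cbind(X_cov, set_hits = hits)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged) return(c(z = NA_real_, p = NA_real_))
  k <- ncol(X)
  p1 <- fit$qr$rank
  if (p1 < k) return(c(z = NA_real_, p = NA_real_)) # hit column aliased
  R <- fit$qr$qr[seq_len(p1), seq_len(p1), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov_unscaled <- chol2inv(R)
  pivot <- fit$qr$pivot[seq_len(p1)]
  pos <- which(pivot == k)
  se <- sqrt(cov_unscaled[pos, pos])
  beta <- unname(fit$coefficients[k])
  z <- beta / se
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# dummy-coded covariate design (with intercept) shared by all refits
burden_design <- function(burden, covariates) {
  keep <- covariates[vapply(covariates, function(v)
    length(unique(burden[[v]])) > 1L, logical(1))]
  dat <- burden
  for (v in intersect(keep, c("chip", "study"))) dat[[v]] <- factor(dat[[v]])
  fml <- if (length(keep) > 0) stats::reformulate(keep) else ~1
  stats::model.matrix(fml, dat)
}

#' Threshold profile with permutation-based empirical correction
#'
#' For each selection fraction, fits the burden regression for the observed
#' top-fraction gene set and for `n_perm` random sets of the same size drawn
#' by shuffling the ranking universe, then converts the observed asymptotic
#' p-value into an empirical one: the fraction of random sets at least as
#' significant. This removes background enrichment — burden signal that any
#' gene set of that size would show (e.g. because cases carry larger CNVs).
#' The signed display statistic is `-log10(empirical_p) * sign(observed_z)`,
#' with `empirical_p` floored at `1/n_perm` for display so a zero count does
#' not produce an infinity.
#'
#' Permuted refits reuse the fixed covariate design and the cached
#' subject-by-gene hit matrix; only the hit-count column changes. The null
#' distributions are computed once per fraction and shared by any observed
#' sets profiled at that fraction.
#'
#' @param ranking ranked gene table from [collapse_to_genes()], or a list of
#'   them (one per condition label).
#' @param annotated annotated, filtered CNVs (stratify before calling for
#'   deletion/duplication profiles).
#' @param subjects subject data.frame.
#' @param fractions selection fractions (default the standard 1-25% grid).
#' @param n_perm number of permutations (2000 in a full analysis; smaller
#'   values are appropriate for simulation studies).
#' @param seed integer seed for the permutation stream.
#' @param stratum label carried into the output.
#' @param covariates covariate columns, as in [fit_enrichment()].
#' @param direction if "p" (default), "as or more significant" compares
#'   two-tailed p-values; if "signed", a null counts only when its z is at
#'   least as extreme *in the observed direction*.
#' @param empirical_mode passed to [empirical_pvalue()].
#' @return data.frame with one row per (condition, fraction): `set_label`,
#'   `stratum`, `fraction`, `n_set`, `observed_z`,
#'   `observed_p`, `empirical_p`, `signed_log_stat`, `n_permutations`,
#'   `n_dropped` (non-estimable permuted fits, excluded from the null; the
#'   profile row is flagged if > 1% drop).
#' @export
threshold_profile <- function(ranking, annotated, subjects,
                              fractions = c(0.01, 0.02, 0.05, 0.10, 0.15,
                                            0.20, 0.25),
                              n_perm = 2000L, seed = 1L,
                              stratum = "all",
                              covariates = c("total_cnv_kb",
                                             "total_genes_hit",
                                             "chip", "study"),
                              direction = c("p", "signed"),
                              empirical_mode = "plain") {
  direction <- match.arg(direction)
  rankings <- if (is.data.frame(ranking)) list(gene_set = ranking) else ranking
  universe <- sort(unique(unlist(lapply(rankings, `[[`, "human_gene_id"))))
  M <- subject_gene_matrix(subjects, annotated, universe)
  # covariates are fixed across all sets: build the burden frame once with
  # an arbitrary set, then swap the hit column
  base_burden <- build_burden_table(subjects, annotated, universe[1],
                                    stratum = "all")
  X_cov <- burden_design(base_burden, covariates)
  y <- base_burden$phenotype

  hits_for <- function(members) {
    idx <- match(members, universe)
    idx <- idx[!is.na(idx)]
    as.vector(Matrix::rowSums(M[, idx, drop = FALSE]))
  }

  perms <- permute_gene_sets(universe, fractions, n_perm, seed = seed)
  null_stats <- lapply(as.character(fractions), function(f) {
    t(vapply(perms, function(pm) fast_burden_fit(y, X_cov, hits_for(pm[[f]])),
             c(z = 0, p = 0)))
  })
  names(null_stats) <- as.character(fractions)

  rows <- list()
  for (lab in names(rankings)) {
    rk <- rankings[[lab]]
    for (f in fractions) {
      gs <- select_top_fraction(rk, f, label = lab)
      obs <- fast_burden_fit(y, X_cov, hits_for(gs$members))
      nulls <- null_stats[[as.character(f)]]
      ok <- !is.na(nulls[, "p"])
      n_dropped <- sum(!ok)
      if (is.na(obs[["p"]])) {
        emp <- NA_real_
        sls <- NA_real_
      } else if (direction == "p") {
        emp <- empirical_pvalue(obs[["p"]], nulls[ok, "p"],
                                mode = empirical_mode)
        sls <- signed_log_stat(emp, obs[["z"]], sum(ok))
      } else {
        zo <- obs[["z"]]
        zn <- nulls[ok, "z"]
        k <- if (zo >= 0) sum(zn >= zo) else sum(zn <= zo)
        emp <- if (empirical_mode == "plain") k / sum(ok)
               else (k + 1) / (sum(ok) + 1)
        sls <- signed_log_stat(emp, zo, sum(ok))
      }
      flag <- if (n_dropped > 0.01 * n_perm) "high_drop_rate" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        set_label = lab, stratum = stratum, fraction = f,
        n_set = length(gs$members),
        observed_z = obs[["z"]], observed_p = obs[["p"]],
        empirical_p = emp, signed_log_stat = sls,
        n_permutations = sum(ok), n_dropped = n_dropped,
        flag = flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -log10 of the empirical p, floored at 1/n so a zero permutation count
# stays finite, signed by the enrichment direction
signed_log_stat <- function(empirical_p, observed_z, n_perm) {
  p <- max(empirical_p, 1 / n_perm)
  -log10(p) * sign(observed_z)
}

#' Plot a threshold profile
#'
#' Signed log empirical p-value against selection fraction, one panel per
#' condition, with the 0.05 significance threshold marked in both
#' directions.
#'
#' @param profile output of [threshold_profile()].
#' @return A ggplot object.
#' @export
plot_threshold_profile <- function(profile) {
  thr <- -log10(0.05)
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = fraction, y = signed_log_stat)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~set_label) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "top fraction of ranked genes",
                  y = expression(-log[10](italic(P)[emp]) %*% sgn(italic(Z)))) +
    ggplot2::theme_bw()
}
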