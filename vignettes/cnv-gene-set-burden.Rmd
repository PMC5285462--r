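---
title: "Linking expression-derived gene sets to CNV burden: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking expression-derived gene sets to CNV burden: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

## The question the pipeline answers

Case-control studies of copy number variants (CNVs) ask whether patients'
deletions and duplications preferentially hit particular groups of genes.
This package implements one specific form of that question: take gene sets
defined by *functional experiments* — genes differentially expressed in the
hippocampus after distinct phases of associative learning (memory
consolidation, retrieval, and extinction), measured on a two-normalization
microarray — map them to human genes, and test whether case CNVs are
enriched for each set relative to control CNVs, adjusting for overall CNV
burden and cohort structure, with a permutation-based empirical correction
that subtracts the enrichment any gene set of that size would show.

The pipeline has four stages, each exposed as package functions and driven
by the numbered scripts under `analysis/`:

1. **Gene ranking** (`filter_probes`, `fisher_combine`, `simes_combine`,
   `collapse_to_genes`, `select_top_fraction`): probe-level p-value pairs
   become a ranked human gene list and top-fraction gene sets.
2. **CNV processing** (`read_cnv_file`, `filter_cnvs`, `annotate_cnvs`,
   `stratify_by_type`): parse, reliability-filter and gene-annotate calls.
3. **Enrichment** (`build_burden_table`, `fit_enrichment`,
   `per_gene_enrichment`): the covariate-adjusted logistic burden test.
4. **Permutation correction** (`permute_gene_sets`, `empirical_pvalue`,
   `threshold_profile`): the empirical null of random same-size sets.

A synthetic-data generator (`sim_config`, `gen_gene_annotation`,
`gen_homology_table`, `gen_probe_stats`, `gen_cnv_cohort`, `run_simulate`)
produces every input with known planted structure, so the full chain is
testable without any external download.

## Gene ranking

Each probe set carries two p-values for differential expression, one per
normalization procedure (MAS5.0-style and RMA-style). The two are combined
with Fisher's method for $k = 2$ tests:

$$X = -2(\ln p_1 + \ln p_2) \sim \chi^2_4 \quad\text{under } H_0,$$

and the combined p-value is the upper-tail probability of $\chi^2_4$ at
$X$. Because the p-values encode two-sided significance of differential
expression in either direction, no sign is retained; genes are ranked by
significance alone.

Probes that do not target a unique gene are removed first. When several
probe sets target one gene, their Fisher-combined p-values are collapsed
with the Simes procedure: with order statistics
$p_{(1)} \le \dots \le p_{(m)}$, the gene-level p-value is
$\min_i \, m\,p_{(i)}/i$, capped at 1. Simes is valid under independence or
positive dependence, which suits probe sets measuring one transcript. With
a single probe the collapse is the identity.

Source-species genes map to human genes through a HomoloGene-style table.
Uniqueness is enforced **in both directions** by default: a source gene
mapping to several human genes is dropped, and so is any human gene
receiving several source genes. The one-directional rule (drop only
multi-mapping source genes) is available via
`collapse_to_genes(..., bidirectional = FALSE)`; we made the stricter rule
the default because a human gene fed by two source genes would otherwise
enter the ranking twice under one identity, double-counting its evidence.

A gene set is the top `floor(fraction * N)` genes of the ranking. Floor
rounding is conservative and deterministic; ties at the cutoff are broken
lexicographically by gene identifier so repeated runs select identical
sets. P-values below $10^{-300}$ are clamped before log transforms (with a
warning) purely for numerical safety.

## CNV processing

Input CNVs use the PLINK-style `.cnv` dialect (1-based inclusive
coordinates, TYPE 1 = deletion, 3 = duplication, SITES = supporting probe
count). Length is computed on that convention as $end - start + 1$.
Internally all interval work is delegated to `GenomicRanges`, with BED
input converted from 0-based half-open coordinates at the file boundary
only — a single internal convention prevents off-by-one drift.

The reliability filter retains calls **at least 100 kb long and covered by
at least 15 probes**, both thresholds inclusive and configurable. A gene is
"hit" when it shares at least one base with the CNV; a minimum
gene-coverage fraction is available (`min_overlap_frac`) but defaults to
any-overlap, since requiring full coverage or exon-level overlap is a
stronger assumption than the data usually support. Sex chromosomes receive
no special handling. When cohorts are annotated on different genome
builds, each must be annotated against its own build's gene intervals and
merged on human gene identifiers afterwards; the package deliberately does
not lift coordinates over between builds.

## The burden regression

The unit of analysis is the subject. For a gene set $S$, subject $i$
contributes

* $h_i$ — the number of *distinct* genes of $S$ overlapped by any of their
  filtered CNVs (a gene hit by two CNVs counts once),
* total CNV kilobases, total distinct genes hit (from the full annotation,
  not just the ranking universe — overall gene load is a property of the
  CNVs, not of the expression experiment),
* chip type and study as dummy-coded factors.

Case-control status is regressed on $h_i$ and the covariates by
maximum-likelihood logistic regression; the reported test is the two-tailed
Wald test on the $h_i$ coefficient (a likelihood-ratio variant would be a
one-line change; Wald is standard for this model family and matches how
the per-gene decomposition is read). Primary analyses over the three
condition sets are Bonferroni-corrected with family size $m = 3$ by
default (configurable — e.g. $m = 9$ if all three strata are treated as
one family).

Subjects without CNVs are retained with zero burden: excluding them would
condition on CNV carriage, which changes the estimand. "Number of genes
per CNV" is implemented as the per-subject total of distinct genes hit —
the outcome is a subject property, so covariates must be subject-level
aggregates; a per-subject *mean genes per CNV* reading would discard the
number of CNVs and is not the default.

Degenerate designs are flagged rather than returned as NaN: constant hit
counts (`constant_predictor`), one-class outcomes
(`single_class_outcome`), non-convergence, and (quasi-)separation
(detected by coefficient magnitude, standard-error blow-up, or fitted
probabilities at the boundary). Single-level factors are dropped with a
message.

Deletions and duplications are disjoint strata; their burden tables are
additive in the count columns, and each stratum is analyzed by simply
restricting the annotated CNVs before aggregation.

## Permutation empirical correction

Asymptotic p-values from the burden regression answer "is this set
enriched beyond its covariate-predicted burden", but any gene set of equal
size shares some *background enrichment* — for example, when cases carry
larger CNVs, every set's hit count associates with case status through
residual confounding the covariates do not fully absorb. The empirical
correction removes it: the entire ranking universe is shuffled `n_perm`
times (2000 in a full analysis); each shuffle's top fractions form nested
random sets of exactly matching sizes; each random set is refit with the
*same fixed covariate structure*; and the empirical p-value is the
fraction of random sets at least as significant as the observed set (ties
count). The default compares two-tailed p-values; a direction-respecting
mode (`direction = "signed"`, counting only nulls at least as extreme in
the observed direction) is available because the signed display statistic
suggests direction matters to readers — p-comparison remains the default
as the plainer reading of "as or more significant".

Three implementation commitments matter for correctness and speed:

* **Caching contract.** Per-subject hit counts against permuted sets are
  computed from a sparse subject-by-gene incidence matrix built once from
  the annotated CNVs (`subject_gene_matrix`); permutation never
  re-annotates CNVs. A unit test verifies the cached path reproduces naive
  per-set recomputation exactly.
* **Shared nulls.** The permutation null at each fraction is generated
  once and shared by all condition rankings profiled together, matching
  the definition (random sets of the same size from the same universe) and
  saving a factor equal to the number of conditions.
* **Drop handling.** Permuted fits that are non-estimable are excluded
  from the null with a logged count; a profile row with more than 1% drops
  is flagged.

The display statistic is $-\log_{10}(P_{emp}) \times \mathrm{sgn}(Z)$ with
$P_{emp}$ floored at $1/n_{perm}$, so an observed set more significant than
every permutation plots at a finite height instead of infinity. The plain
$k/N$ estimator is the default (it can return exactly 0, matching how such
results are usually printed); the $(k+1)/(N+1)$ estimator is available as
`mode = "add_one"`.

## What the synthetic generator emulates — and what it does not

`gen_cnv_cohort` generates phenotype **conditionally on CNV burden**: each
subject's linear predictor is
$\alpha + \beta_{planted} h_i + \beta_{bg} g_i$, where $h_i$ counts
distinct planted-set genes hit by the subject's *filter-passing* CNVs and
$g_i$ the total distinct genes hit, and $\alpha$ is solved numerically so
the expected case fraction matches the configured cohort composition. Two
design choices deserve emphasis:

* Generating phenotype from burden (rather than burden from phenotype)
  makes the planted $\beta_{planted}$ the literal estimand of the
  downstream regression, enabling exact parameter-recovery tests.
* Counting $h_i$ on filter-passing calls means the causal pathway runs
  through exactly the calls the analysis sees, so recovery tests are not
  diluted by sub-threshold calls the analysis never observes.

CNV size confounding is induced *after* phenotype assignment by scaling
case CNV lengths up (default factor 1, i.e. off); the enlarged intervals
genuinely hit more genes, which is precisely the confound the covariates
must absorb. The `background_log_or` field gives every gene a uniform
case-burden effect — the situation the permutation correction exists to
handle.

Signal probes draw both normalization p-values from one latent normal
shifted by `signal_effect` (default 3 SD) with independent channel noise,
reproducing correlated-but-not-identical p-value pairs without modeling
raw intensities. Null probes are independent Uniform(0,1) pairs.

Default study conditions (chosen once, as a scaled but structurally
faithful cohort): 1000 genes over 5 chromosomes of 25 Mb (about one gene
per 125 kb); 2 CNV calls per subject on average with lognormal lengths
around 200 kb (so roughly 90% pass the 100 kb filter) and 0.2 probes per
kb (200 kb ⇒ 40 probes); three studies and two chip types assigned
independently of phenotype; a planted set of 5% of genes with log OR
log(2) per gene hit; expression signal in 5% of genes. The end-to-end
analyses use 2500 cases and 2500 controls; the calibration simulations in
the test suite use 500 + 500 (type-I error, confounding control) and
150 + 150 (permutation calibration, where each replicate carries 200
permutations). These sizes give stable rates at reasonable cost and are
stated here as the package's simulation design.

The generator does **not** emulate: raw array intensities, linkage
disequilibrium, recurrent CNV hotspots or breakpoint clustering,
length-dependent gene density, ancestry structure, or batch effects
correlated with phenotype. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the stated
generative model — not that real CNV calls are free of the artifacts those
phenomena produce.

## Numerical and degenerate-input choices

* P-value floor $10^{-300}$ before logs; warned when applied.
* The logistic intercept solver falls back to the closed form
  $\alpha = \mathrm{logit}(f) - \eta$ when burden is constant (e.g. a
  cohort with no CNVs), where `uniroot` would otherwise see a flat
  function.
* `filter_cnvs` thresholds are inclusive on both sides; the boundary
  fixture under `inst/extdata/` pins this.
* Probe counts of generated CNVs are `max(1, round(rate * kb))`, hence
  monotone in length at fixed rate.
* Empirical p-values with zero exceedances are reported as 0 in plain
  mode; only the *display* statistic applies the $1/n_{perm}$ floor.

## Known limitations

* The Wald test can be conservative in small strata with rare hit counts;
  for per-gene decompositions with very few carriers the flagged
  separation diagnostics should be taken seriously rather than the point
  estimates.
* Bonferroni family size is a judgment call (3 condition sets by default);
  analyses spanning strata or fraction grids should rely on the
  permutation-corrected profile instead, which is why it exists.
* Permutations shuffle genes uniformly; gene-length-matched permutation
  schemes are out of scope, so very long genes contribute equally to
  observed and null sets only on average.

## Reproducing the validation numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
validation quantity from scratch: null type-I error (500 cohorts),
planted-effect recovery and power (100 cohorts of 5000 subjects),
paired confounding control (300 cohorts), permutation calibration
(100 runs) and background-enrichment removal (50 runs), the three-condition
threshold profile, and the boundary-fixture filter count. The same checks
run as the acceptance block of the test suite.
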