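# cnvburden

Gene-set burden analysis of case-control copy number variants (CNVs) with
gene sets derived from functional gene-expression experiments.

## The problem

Rare CNVs — deletions and duplications of 100 kb and more — are enriched in
several psychiatric disorders, but a burden signal alone does not say which
biological processes the variants disturb. One way to ask a sharper
question is to define gene sets *functionally*: take the genes
differentially expressed in the hippocampus after specific phases of
associative learning (consolidation, retrieval, extinction of a
conditioned fear memory), map them to human genes, and test whether
patients' CNVs hit those genes more often than controls' CNVs, beyond what
overall CNV burden explains. This package implements that full analysis
chain for anyone with (i) per-subject CNV calls and (ii) probe-level
differential-expression p-values from a two-normalization microarray
analysis — plus a synthetic-data generator that plants known structure so
the entire pipeline is testable without any external data.

## The method

**Gene ranking.** Each probe set carries two p-values (one per
normalization, e.g. MAS5.0 and RMA). They are combined with Fisher's
method, X = −2(ln p₁ + ln p₂) ~ χ²₄; genes with several probe sets are
collapsed with the Simes procedure, min over i of m·p₍ᵢ₎/i; source-species
genes map to human genes through a HomoloGene-style table with uniqueness
enforced in both directions; the top `floor(f·N)` genes at fractions
1–25% form the candidate gene sets.

**Burden regression.** For gene set S, case-control status is regressed on
the per-subject count of distinct S-genes overlapped by filtered CNVs
(≥ 100 kb, ≥ 15 probes), adjusting for total CNV kb, total distinct genes
hit, chip type and study. Two-tailed Wald test on the gene-set
coefficient; Bonferroni over the set family; deletions and duplications
also analyzed separately.

**Permutation correction.** The ranking universe is shuffled 2000 times;
each shuffle's top fractions give random gene sets of exactly matching
size, refit with the same covariates; the empirical p is the fraction of
random sets as or more significant. This subtracts background enrichment —
the signal any same-size set shows, e.g. when cases simply carry larger
CNVs. Profiles are displayed as −log₁₀(P_emp) × sgn(Z).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R` … `04_profile.R`). In miniature:

```r
library(cnvburden)

cfg <- sim_config(n_cases = 2500, n_controls = 2500, seed = 2026)
sim <- run_simulate(cfg, "results/simulated")   # genes, probes, homology, CNVs

rk  <- run_rank(sim$paths$probes_extinction, sim$paths$homology,
                "results/ranked", "extinction")

ann <- annotate_cnvs(filter_cnvs(sim$cohort$cnvs), sim$genes)
b   <- build_burden_table(sim$cohort$subjects, ann, rk$sets[["0.05"]])
fit_enrichment(b, set_label = "extinction")
```

```
   set_label stratum     beta         se        z            p  p_corrected
1 extinction     all 0.655429 0.07801011 8.401848 4.395075e-17 1.318522e-16
  n_case n_control flag
1   2488      2512
```

The planted causal set carries log OR = log(2) ≈ 0.693 per gene hit; the
top-5% extinction set recovers 78% of the planted genes (the rest are lost
to homology filtering and signal noise, slightly attenuating the
coefficient), and the burden test detects the enrichment at
p ≈ 4×10⁻¹⁷. The same
cohort's consolidation and retrieval rankings — whose signal genes are
unrelated to phenotype — stay flat, and the permutation profile of
`analysis/04_profile.R` shows only the extinction curve crossing the 0.05
empirical threshold across the 1–25% grid.

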