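#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Produces a gene annotation (BED), a homology table, three probe-level
# differential-expression tables (one per learning condition: extinction,
# consolidation, retrieval), and a case-control CNV cohort in which the
# extinction-condition signal genes are planted as a causal gene set with a
# log odds ratio of log(2) per gene hit. All downstream stages read only
# these files.

suppressMessages(library(cnvburden))

cfg <- sim_config(n_cases = 2500, n_controls = 2500, seed = 2026)
print(cfg)

sim <- run_simulate(cfg, "results/simulated")

cat("\nWrote to results/simulated/:\n")
for (p in unlist(sim$paths)) cat(" ", p, "\n")
cat(sprintf("\nCohort: %d subjects, %d CNV calls (%d pass the 100 kb / 15 probe filter)\n",
            nrow(sim$cohort$subjects), nrow(sim$cohort$cnvs),
            nrow(filter_cnvs(sim$cohort$cnvs, quiet = TRUE))))
cat(sprintf("Planted causal set: %d genes, log OR %.3f per gene hit\n",
            length(sim$planted), cfg$planted_log_or))
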