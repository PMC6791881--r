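#!/usr/bin/env Rscript
# Stage 1: draw the synthetic study cohorts at the default design scale
# (43 individuals x 4 quarterly visits x 35 subsets; 40 control-sample runs;
# 37 two-sibling families) and deposit them as CSV plus ground-truth JSON
# under results/data/ for the later stages.

suppressPackageStartupMessages(library(cytomevar))
seed <- 42L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
write_generator_config(cfg, file.path(out, "generator_config.json"))

coh <- generate_cohort(cfg)
reps <- generate_replicates(cfg)
sib <- generate_siblings(cfg)

write_table(coh$observations, file.path(out, "observations.csv"))
write_table(reps$replicates, file.path(out, "replicates.csv"))
write_table(sib$siblings, file.path(out, "siblings.csv"))
write_table(default_subset_catalog(), file.path(out, "catalog.csv"))
jsonlite::write_json(coh$truth$baselines, file.path(out, "truth_baselines.json"),
                     digits = NA, dataframe = "columns")

rep_comp <- completeness_report(coh$observations)
cat(sprintf("cohort: %d individuals x %d visits x %d subsets (%d rows), complete grid: %s\n",
            length(unique(coh$observations$individual_id)), cfg$n_visits,
            nrow(cfg$subsets), nrow(coh$observations), rep_comp$complete))
cat(sprintf("replicates: %d runs; siblings: %d families, %d individuals\n",
            cfg$n_replicate_runs, cfg$n_families,
            length(unique(sib$siblings$individual_id))))
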