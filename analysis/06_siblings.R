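#!/usr/bin/env Rscript
# Stage 6: sibling-pair concordance — compare the z-score distance within
# sibling pairs against disjoint unrelated pairs resampled from visit 1 of
# the longitudinal cohort, per subset, with BH q-values.

suppressPackageStartupMessages(library(cytomevar))
seed <- 42L
obs <- read_observations("results/data/observations.csv")
sib <- read_siblings("results/data/siblings.csv")
excluded <- unlist(jsonlite::read_json("results/exclusions.json")$excluded)
obs <- obs[!obs$subset_id %in% excluded, ]
sib <- sib[!sib$subset_id %in% excluded, ]

res <- suppressMessages(
  sibling_concordance_all(sib, obs, n_resamples = 999, seed = seed,
                          reference_visit = 1, subsample_pairs = TRUE))
write_table(res, "results/sibling_results.csv")

conc <- res$subset_id[res$q_value < 0.05]
cat(sprintf("%d/%d subsets are more concordant in siblings than in unrelated pairs (q < 0.05):\n",
            length(conc), nrow(res)))
cat(" ", paste(sort(conc), collapse = ", "), "\n")
cat(sprintf("(%d sibling pairs per subset after matching the %d-individual reference)\n",
            res$n_pairs[1], length(unique(obs$individual_id))))
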