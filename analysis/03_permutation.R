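#!/usr/bin/env Rscript
# Stage 3: per-subset permutation test of whether between-individual variance
# exceeds within-individual variance, with BH q-values across subsets.

suppressPackageStartupMessages(library(cytomevar))
seed <- 42L
obs <- read_observations("results/data/observations.csv")
excluded <- unlist(jsonlite::read_json("results/exclusions.json")$excluded)
obs <- obs[!obs$subset_id %in% excluded, ]

norm <- mean_normalize(obs)
res <- permutation_test_all(norm, n_permutations = 999, seed = seed)
write_table(res, "results/permtest_results.csv")

sig <- res$q_value < 0.05
cat(sprintf("%d/%d subsets show between-individual variance exceeding within (q < 0.05, B = 999)\n",
            sum(sig), nrow(res)))
top <- res[order(res$p_value), ][1:5, c("subset_id", "observed_stat", "p_value", "q_value")]
cat("strongest between-dominated subsets:\n")
print(top, row.names = FALSE)
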