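#!/usr/bin/env Rscript
# Stage 2: mean-normalize, estimate between/within/technical variances and
# REML variance components per subset, flag technical-outlier subsets, and
# regress within-individual on between-individual variance across subsets.

suppressPackageStartupMessages(library(cytomevar))
data_dir <- "results/data"
out <- "results"
catalog <- read_catalog(file.path(data_dir, "catalog.csv"))
obs <- read_observations(file.path(data_dir, "observations.csv"), catalog)
reps <- read_replicates(file.path(data_dir, "replicates.csv"), catalog)

summ <- variance_summary(obs, reps)
write_table(summ, file.path(out, "variance_summary.csv"))

flags <- detect_outlier_subsets(summ, field = "var_technical", fence = 3)
excluded <- flags$subset_id[flags$flagged]
jsonlite::write_json(list(field = "var_technical", fence = 3,
                          excluded = excluded),
                     file.path(out, "exclusions.json"), auto_unbox = TRUE)
kept <- summ[!summ$subset_id %in% excluded, ]

fit <- regress_within_on_between(kept)
fit_tech <- regress_within_on_between(kept, adjust_technical = TRUE)
jsonlite::write_json(list(unadjusted = fit, adjusted = fit_tech),
                     file.path(out, "regression.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("technical-outlier subsets excluded (Tukey Q3 + 3 IQR): %s\n",
            if (length(excluded)) paste(excluded, collapse = ", ") else "none"))
cat(sprintf("median prop_within across %d retained subsets: %.2f (most variance sits between individuals)\n",
            nrow(kept), median(kept$prop_within, na.rm = TRUE)))
cat(sprintf("within ~ between regression: slope %.2f, adjusted R^2 %.2f, t = %.1f (p = %.2g)\n",
            fit$slope, fit$adjusted_r_squared, fit$t_value, fit$p_value))
cat(sprintf("with technical covariate:    adjusted R^2 %.2f, t = %.1f\n",
            fit_tech$adjusted_r_squared, fit_tech$t_value))
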