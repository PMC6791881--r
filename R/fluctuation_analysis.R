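#' Z-score frequencies per subset across the whole cohort
#'
#' For each subset, over all individuals and visits: `z = (y - mean) / SD`
#' (n-1 SD), so each subset's z-scores have mean 0 and SD 1 and baselines/
#' fluctuations become comparable across subsets of very different
#' population size.
#'
#' @param obs validated observation table.
#' @return the table with an added `z` column.
#' @export
zscore_transform <- function(obs) {
  counts <- table(obs$subset_id)
  if (any(counts < 2L)) {
    validation_error("zscore_transform: subset(s) with fewer than 2 observations: ",
                     paste(names(counts)[counts < 2L], collapse = ", "))
  }
  sds <- tapply(obs$frequency_pct, obs$subset_id, stats::sd)
  zero <- names(sds)[sds == 0]
  if (length(zero) > 0L) {
    validation_error("zscore_transform: zero SD for subset(s): ",
                     paste(zero, collapse = ", "))
  }
  means <- tapply(obs$frequency_pct, obs$subset_id, mean)
  obs$z <- (obs$frequency_pct - as.numeric(means[obs$subset_id])) /
    as.numeric(sds[obs$subset_id])
  obs
}

#' Per-individual baseline and fluctuation statistics
#'
#' For each (individual, subset): the baseline is the mean of that
#' individual's z-scores across visits; the fluctuation is their sample
#' variance (n-1), `NA` for individuals with a single visit. The
#' `"variance_over_mean"` variant instead reports the per-individual variance
#' of raw frequencies divided by their mean (a dispersion-index reading of
#' "fluctuation"); the z-variance definition is the default.
#'
#' @param z z-scored observation table (from [zscore_transform()]).
#' @param variant `"z_variance"` (default) or `"variance_over_mean"`.
#' @return data frame: `individual_id, subset_id, baseline_z_mean,
#'   fluctuation_z_var, n_visits_used`.
#' @export
individual_baseline_fluctuation <- function(z,
                                            variant = c("z_variance",
                                                        "variance_over_mean")) {
  variant <- match.arg(variant)
  stopifnot("z" %in% names(z))
  key <- interaction(z$individual_id, z$subset_id, drop = TRUE, sep = "\r")
  out <- lapply(split(z, key), function(d) {
    fluct <- if (variant == "z_variance") {
      sample_var(d$z)
    } else {
      v <- sample_var(d$frequency_pct)
      if (is.na(v)) NA_real_ else v / mean(d$frequency_pct)
    }
    data.frame(individual_id = d$individual_id[1L],
               subset_id = d$subset_id[1L],
               baseline_z_mean = mean(d$z),
               fluctuation_z_var = fluct,
               n_visits_used = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$subset_id, out$individual_id), ]
  rownames(out) <- NULL
  out
}

#' Mean-variance coupling per subset (Spearman)
#'
#' Correlates each individual's baseline (mean z-score) with their
#' fluctuation (variance of z-scores) across individuals, for one subset.
#' A significantly positive rho is the environmental-responsiveness
#' signature: individuals sitting high also fluctuate more. Spearman with
#' average ranks for ties; exact permutation p for n < 10, t approximation
#' otherwise (see [spearman_test()]).
#'
#' @param summ fluctuation summary from [individual_baseline_fluctuation()].
#' @param subset_id subset to test.
#' @return one-row data frame: `subset_id, spearman_rho, p_value, n_individuals`.
#' @export
mean_variance_correlation <- function(summ, subset_id) {
  d <- summ[summ$subset_id == subset_id &
              stats::complete.cases(summ[c("baseline_z_mean", "fluctuation_z_var")]),
            , drop = FALSE]
  if (nrow(d) < 5L) {
    validation_error("mean_variance_correlation: need >= 5 individuals with ",
                     "both statistics for subset ", subset_id)
  }
  st <- spearman_test(d$baseline_z_mean, d$fluctuation_z_var)
  data.frame(subset_id = subset_id, spearman_rho = st$rho,
             p_value = st$p_value, n_individuals = st$n,
             stringsAsFactors = FALSE)
}

#' Mean-variance coupling for every subset
#' @inheritParams mean_variance_correlation
#' @param subset_ids subsets to test (default all in `summ`).
#' @return data frame, one row per subset.
#' @export
mean_variance_correlation_all <- function(summ,
                                          subset_ids = unique(summ$subset_id)) {
  out <- do.call(rbind, lapply(subset_ids, function(s) {
    mean_variance_correlation(summ, s)
  }))
  rownames(out) <- NULL
  out
}

#' Rank concordance of inter-individual variance with mean-variance coupling
#'
#' Tests whether subsets with high between-individual variance are also the
#' subsets whose individuals show strong mean-variance coupling: Spearman
#' correlation between the rank of `var_between` and the rank of the
#' per-subset mean-variance `spearman_rho`, across subsets.
#'
#' @param var_summaries variance summary table (needs `subset_id`,
#'   `var_between`).
#' @param mv mean-variance correlation table (needs `subset_id`,
#'   `spearman_rho`).
#' @return list: `rho`, `p_value`, `n_subsets`.
#' @export
rank_concordance <- function(var_summaries, mv) {
  a <- setdiff(var_summaries$subset_id, mv$subset_id)
  b <- setdiff(mv$subset_id, var_summaries$subset_id)
  if (length(a) > 0L || length(b) > 0L) {
    validation_error("rank_concordance: subset sets differ; only in variance ",
                     "table: [", paste(a, collapse = ", "), "]; only in ",
                     "mean-variance table: [", paste(b, collapse = ", "), "]")
  }
  m <- merge(var_summaries[c("subset_id", "var_between")],
             mv[c("subset_id", "spearman_rho")], by = "subset_id")
  st <- spearman_test(m$var_between, m$spearman_rho)
  list(rho = st$rho, p_value = st$p_value, n_subsets = st$n)
}
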