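# enumerate every distinct assignment of the observation indices to the
# individual slots (group sizes fixed) and return the test statistic for each
enumerate_assignment_stats <- function(values, sizes, stat_fun) {
  out <- numeric(0)
  rec <- function(avail, sizes, acc) {
    if (length(sizes) == 0L) {
      out[[length(out) + 1L]] <<- stat_fun(acc)
      return(invisible(NULL))
    }
    for (pick in utils::combn(seq_along(avail), sizes[1L], simplify = FALSE)) {
      rec(avail[-pick], sizes[-1L], c(acc, list(values[avail[pick]])))
    }
    invisible(NULL)
  }
  rec(seq_along(values), sizes, list())
  unlist(out)
}

# number of distinct label assignments: n! / prod(sizes!)
n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# T = var_between - var_within from a list of per-individual value vectors
between_minus_within <- function(groups) {
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, sample_var, numeric(1))
  sample_var(m) - mean(v[!is.na(v)])
}

#' Permutation test: does between-individual variance exceed within?
#'
#' The test statistic is `T = var_between - var_within` on mean-normalized
#' values (between = variance of per-individual means, within = unweighted
#' mean of per-individual variances). The null destroys individual identity
#' by randomly permuting which observations belong to which individual,
#' preserving every individual's visit count and the marginal distribution of
#' values. One-sided p-value with the add-one convention,
#' `p = (1 + #(T_null >= T_obs)) / (B + 1)`, so `p >= 1/(B+1)`.
#'
#' When the number of distinct label assignments on a small input does not
#' exceed `n_permutations`, the null is enumerated exhaustively (with a
#' notice) and `p` is the exact fraction of assignments with `T >= T_obs`.
#'
#' @param norm mean-normalized observation table (needs `value`).
#' @param subset_id subset to test.
#' @param n_permutations number of random permutations (>= 99).
#' @param seed RNG seed recorded in the result.
#' @return one-row data frame: `subset_id, observed_stat, null_mean, null_sd,
#'   p_value, n_permutations, exhaustive, seed`.
#' @export
permutation_test_variance <- function(norm, subset_id, n_permutations = 9999L,
                                      seed = 1L) {
  if (n_permutations < 99L) {
    validation_error("permutation_test_variance: n_permutations must be >= 99")
  }
  d <- norm[norm$subset_id == subset_id, , drop = FALSE]
  if (nrow(d) == 0L) validation_error("no observations for subset ", subset_id)
  g <- factor(d$individual_id)
  sizes <- as.integer(table(g))
  if (sum(sizes >= 2L) < 3L) {
    validation_error("permutation_test_variance: need >= 3 individuals with >= 2 visits")
  }
  y <- d$value
  k <- nlevels(g)
  gi <- as.integer(g)
  observed <- between_minus_within(split(y, gi))
  n_distinct <- n_assignments(sizes)
  if (n_distinct <= n_permutations) {
    message("permutation_test_variance: only ", round(n_distinct),
            " distinct assignments; enumerating exhaustively")
    t_all <- enumerate_assignment_stats(y, sizes, between_minus_within)
    p <- mean(t_all >= observed - 1e-12)
    return(data.frame(subset_id = subset_id, observed_stat = observed,
                      null_mean = mean(t_all), null_sd = stats::sd(t_all),
                      p_value = p, n_permutations = length(t_all),
                      exhaustive = TRUE, seed = as.integer(seed),
                      stringsAsFactors = FALSE))
  }
  n <- length(y)
  t_null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      yp <- y[sample.int(n)]
      mo <- group_moments(yp, gi, k)
      ok <- mo$n >= 2L
      sample_var(mo$mean) - mean(mo$var[ok])
    }, numeric(1))
  })
  p <- (1 + sum(t_null >= observed - 1e-12)) / (n_permutations + 1)
  data.frame(subset_id = subset_id, observed_stat = observed,
             null_mean = mean(t_null), null_sd = stats::sd(t_null),
             p_value = p, n_permutations = as.integer(n_permutations),
             exhaustive = FALSE, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Batch permutation tests over all subsets with BH q-values
#'
#' @param norm mean-normalized observation table.
#' @param subset_ids subsets to test (default all in `norm`).
#' @param n_permutations permutations per subset (batch default 999).
#' @param seed master seed; subset `i` uses `seed + i - 1`.
#' @return data frame, one row per subset, with a `q_value` column.
#' @export
permutation_test_all <- function(norm, subset_ids = unique(norm$subset_id),
                                 n_permutations = 999L, seed = 1L) {
  res <- lapply(seq_along(subset_ids), function(i) {
    permutation_test_variance(norm, subset_ids[[i]], n_permutations,
                              seed = seed + i - 1L)
  })
  res <- do.call(rbind, res)
  res$q_value <- fdr_adjust(res$p_value)
  res
}

# z-score a vector (n-1 SD); errors on zero SD
zscore_vec <- function(y, what) {
  s <- stats::sd(y)
  if (is.na(s) || s == 0) {
    validation_error("zero standard deviation in ", what)
  }
  (y - mean(y)) / s
}

#' Sibling-pair concordance test against unrelated-pair resampling
#'
#' Both cohorts are z-scored per subset against their own mean and SD
#' (removing cohort-level location/scale differences). Sibling pairs are all
#' within-family pairs; the observed statistic is the mean absolute z-score
#' difference over those pairs. The null resamples the same number of
#' disjoint unrelated pairs (without replacement within a draw) from one
#' visit of the longitudinal reference cohort. One-sided add-one p-value for
#' concordance: `p = (1 + #(null <= observed)) / (B + 1)` — siblings are
#' concordant when their distance is smaller than unrelated pairs'.
#'
#' @param siblings validated sibling table.
#' @param reference validated observation table (longitudinal cohort).
#' @param subset_id subset to test.
#' @param n_resamples number of null draws (>= 99).
#' @param seed RNG seed recorded in the result.
#' @param reference_visit which visit of the reference cohort supplies the
#'   unrelated individuals (default 1).
#' @param subsample_pairs when the reference cohort cannot supply as many
#'   disjoint unrelated pairs as there are sibling pairs, randomly subsample
#'   the sibling pairs down to `floor(n_reference / 2)` (seeded) instead of
#'   erroring. Default FALSE: a too-small reference is an error.
#' @return one-row data frame: `subset_id, observed_mean_distance, null_mean,
#'   null_sd, p_value, n_pairs, n_resamples, seed`.
#' @export
sibling_concordance_test <- function(siblings, reference, subset_id,
                                     n_resamples = 9999L, seed = 1L,
                                     reference_visit = 1L,
                                     subsample_pairs = FALSE) {
  if (n_resamples < 99L) {
    validation_error("sibling_concordance_test: n_resamples must be >= 99")
  }
  sib <- siblings[siblings$subset_id == subset_id, , drop = FALSE]
  ref <- reference[reference$subset_id == subset_id &
                     reference$visit_index == reference_visit, , drop = FALSE]
  if (nrow(sib) == 0L) validation_error("no sibling records for subset ", subset_id)
  fam_sizes <- tapply(sib$individual_id, sib$family_id,
                      function(x) length(unique(x)))
  small <- names(fam_sizes)[fam_sizes < 2L]
  if (length(small) > 0L) {
    message("excluding ", length(small), " family(ies) with < 2 members")
    sib <- sib[!sib$family_id %in% small, , drop = FALSE]
  }
  # all within-family pairs; the pair count (not family count) is n_pairs
  zs <- zscore_vec(sib$frequency_pct, paste0("sibling cohort subset ", subset_id))
  pairs <- do.call(rbind, lapply(split(seq_len(nrow(sib)), sib$family_id),
                                 function(ix) {
    if (length(ix) < 2L) return(NULL)
    t(utils::combn(ix, 2L))
  }))
  n_pairs <- nrow(pairs)
  if (is.null(n_pairs) || n_pairs < 5L) {
    validation_error("sibling_concordance_test: need >= 5 sibling pairs")
  }
  n_ref <- nrow(ref)
  zr <- zscore_vec(ref$frequency_pct, paste0("reference cohort subset ", subset_id))
  res <- with_seed(seed, {
    if (n_ref < 2L * n_pairs) {
      if (!subsample_pairs || floor(n_ref / 2) < 5L) {
        stop("sibling_concordance_test: reference too small (", n_ref,
             " individuals for ", n_pairs, " disjoint null pairs)",
             call. = FALSE)
      }
      keep <- sample.int(n_pairs, floor(n_ref / 2))
      message("sibling_concordance_test[", subset_id, "]: subsampling ",
              n_pairs, " sibling pairs to ", length(keep),
              " to match the reference cohort")
      pairs <- pairs[keep, , drop = FALSE]
      n_pairs <- nrow(pairs)
    }
    observed <- mean(abs(zs[pairs[, 1L]] - zs[pairs[, 2L]]))
    odd <- seq(1L, 2L * n_pairs, by = 2L)
    null <- vapply(seq_len(n_resamples), function(b) {
      ix <- sample.int(n_ref, 2L * n_pairs)
      mean(abs(zr[ix[odd]] - zr[ix[odd + 1L]]))
    }, numeric(1))
    list(observed = observed, null = null, n_pairs = n_pairs)
  })
  observed <- res$observed
  null <- res$null
  n_pairs <- res$n_pairs
  p <- (1 + sum(null <= observed + 1e-12)) / (n_resamples + 1)
  data.frame(subset_id = subset_id, observed_mean_distance = observed,
             null_mean = mean(null), null_sd = stats::sd(null), p_value = p,
             n_pairs = as.integer(n_pairs),
             n_resamples = as.integer(n_resamples), seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Batch sibling concordance tests with BH q-values
#' @inheritParams sibling_concordance_test
#' @param subset_ids subsets to test (default all in `siblings`).
#' @return data frame, one row per subset, with a `q_value` column.
#' @export
sibling_concordance_all <- function(siblings, reference,
                                    subset_ids = unique(siblings$subset_id),
                                    n_resamples = 999L, seed = 1L,
                                    reference_visit = 1L,
                                    subsample_pairs = FALSE) {
  res <- lapply(seq_along(subset_ids), function(i) {
    sibling_concordance_test(siblings, reference, subset_ids[[i]],
                             n_resamples, seed = seed + i - 1L,
                             reference_visit = reference_visit,
                             subsample_pairs = subsample_pairs)
  })
  res <- do.call(rbind, res)
  res$q_value <- fdr_adjust(res$p_value)
  res
}
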