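# 31-ary polynomial rolling hash of a string (mod 2^31 - 1); fingerprints
# run configurations in the sidecar JSON
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' End-to-end analysis of a longitudinal immunophenotyping study
#'
#' Chains every stage on validated input tables: mean-normalization,
#' descriptive between/within/technical variances, technical-outlier subset
#' exclusion, REML variance components, the within-on-between variance
#' regression, per-subset permutation tests, z-scoring with per-individual
#' baseline/fluctuation statistics and mean-variance coupling, rank
#' concordance, PCA and Spearman correlation networks, sex comparison, and
#' (when a sibling table is given) the sibling concordance tests. Every
#' intermediate table is written under `out_dir` together with a
#' machine-readable `summary.json` carrying the package version, config hash
#' and master seed; the bundle is identical for identical (inputs, config,
#' seed).
#'
#' @param obs validated observation table.
#' @param reps optional validated replicate table.
#' @param siblings optional validated sibling table.
#' @param catalog optional subset catalog (enables compositional-edge
#'   dropping in the network stage).
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param seed master seed for every resampling stage.
#' @param n_permutations permutations per subset for the variance test.
#' @param n_resamples null draws per subset for the sibling test.
#' @param q_threshold,rho_threshold network edge thresholds.
#' @param outlier_fence IQR multiplier of the exclusion fence.
#' @param outlier_field variance field driving exclusion
#'   (default `"var_technical"` when replicates are given, else none).
#' @param reference_visit visit of `obs` used as the unrelated-pair reference.
#' @param drop_same_parent drop compositional (same-gate) network edges.
#' @return list with all stage results (invisibly also written to disk).
#' @export
run_pipeline <- function(obs, reps = NULL, siblings = NULL, catalog = NULL,
                         out_dir = NULL, seed = 1L, n_permutations = 999L,
                         n_resamples = 999L, q_threshold = 0.05,
                         rho_threshold = 0, outlier_fence = 3,
                         outlier_field = if (!is.null(reps)) "var_technical" else NULL,
                         reference_visit = 1L, drop_same_parent = FALSE) {
  stopifnot(q_threshold > 0, q_threshold <= 1, rho_threshold >= 0,
            rho_threshold <= 1, outlier_fence > 0)
  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  emit <- function(tab, name) {
    if (write_out) write_table(tab, file.path(out_dir, name))
  }
  emit_json <- function(x, name) {
    if (write_out) {
      jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }

  # 1-3: normalization, descriptive + model-based variances, exclusions
  summ <- variance_summary(obs, reps)
  exclusions <- NULL
  retained <- summ$subset_id
  if (!is.null(outlier_field)) {
    exclusions <- detect_outlier_subsets(summ, field = outlier_field,
                                         fence = outlier_fence)
    retained <- exclusions$subset_id[!exclusions$flagged]
  }
  emit(summ, "variance_summary.csv")
  emit_json(list(field = outlier_field, fence = outlier_fence,
                 excluded = if (is.null(exclusions)) character(0) else
                   exclusions$subset_id[exclusions$flagged]),
            "exclusions.json")

  obs_kept <- obs[obs$subset_id %in% retained, , drop = FALSE]
  summ_kept <- summ[summ$subset_id %in% retained, , drop = FALSE]

  # 4: within-on-between regression across retained subsets
  regression <- list(
    unadjusted = regress_within_on_between(summ_kept, adjust_technical = FALSE),
    adjusted = if (!is.null(reps))
      regress_within_on_between(summ_kept, adjust_technical = TRUE) else NULL
  )
  emit_json(regression, "regression.json")

  # 5: permutation tests (between vs within variance)
  norm_kept <- mean_normalize(obs_kept)
  permtests <- permutation_test_all(norm_kept, subset_ids = retained,
                                    n_permutations = n_permutations,
                                    seed = seed)
  emit(permtests, "permtest_results.csv")

  # 6: fluctuation statistics and mean-variance coupling
  z <- zscore_transform(obs_kept)
  fluct <- individual_baseline_fluctuation(z)
  emit(fluct, "fluctuation_summary.csv")
  mv <- mean_variance_correlation_all(fluct, subset_ids = retained)
  emit(mv, "meanvar_correlations.csv")
  concordance <- rank_concordance(summ_kept, mv)
  emit_json(concordance, "rank_concordance.json")

  # 7: multivariate structure
  feat_base <- individual_feature_matrix(fluct, "baseline")
  feat_both <- individual_feature_matrix(fluct, "both")
  pca <- pca_individuals(feat_both, standardize = TRUE, impute_mean = TRUE)
  emit(data.frame(individual_id = rownames(pca$scores),
                  as.data.frame(pca$scores[, seq_len(min(5L, ncol(pca$scores))),
                                           drop = FALSE]),
                  stringsAsFactors = FALSE),
       "pca_scores.csv")
  emit(data.frame(component = seq_along(pca$explained_variance_ratio),
                  explained_variance_ratio = pca$explained_variance_ratio),
       "pca_scree.csv")
  cm <- correlation_matrix(feat_base)
  up <- which(upper.tri(cm$rho), arr.ind = TRUE)
  cm_long <- data.frame(subset_a = colnames(cm$rho)[up[, 1L]],
                        subset_b = colnames(cm$rho)[up[, 2L]],
                        rho = cm$rho[up], p = cm$p[up], q = cm$q[up],
                        stringsAsFactors = FALSE)
  emit(cm_long, "correlation_matrix.csv")
  edges <- correlation_network(cm, q_threshold = q_threshold,
                               rho_threshold = rho_threshold,
                               catalog = catalog,
                               drop_same_parent = drop_same_parent)
  emit(edges, "network_edges.csv")

  # 8: sex comparison (skipped when only one sex is present)
  sexes <- setdiff(unique(obs_kept$sex), "unknown")
  groups <- if (length(sexes) == 2L) {
    g <- group_comparison(obs_kept, "sex")
    emit(g, "group_comparison.csv")
    g
  } else NULL

  # 9: sibling concordance
  sib_res <- if (!is.null(siblings)) {
    s <- sibling_concordance_all(
      siblings[siblings$subset_id %in% retained, , drop = FALSE],
      obs_kept, n_resamples = n_resamples, seed = seed,
      reference_visit = reference_visit, subsample_pairs = TRUE)
    emit(s, "sibling_results.csv")
    s
  } else NULL

  config <- list(seed = seed, n_permutations = n_permutations,
                 n_resamples = n_resamples, q_threshold = q_threshold,
                 rho_threshold = rho_threshold, outlier_fence = outlier_fence,
                 outlier_field = outlier_field,
                 reference_visit = reference_visit,
                 drop_same_parent = drop_same_parent)
  run_info <- list(
    package_version = as.character(utils::packageVersion("cytomevar")),
    config = config,
    config_hash = config_hash(jsonlite::toJSON(config, auto_unbox = TRUE)),
    n_individuals = length(unique(obs$individual_id)),
    n_subsets_input = length(unique(obs$subset_id)),
    n_subsets_retained = length(retained)
  )
  emit_json(c(run_info, list(
    regression = regression, rank_concordance = concordance,
    pca_explained_first2 = sum(pca$explained_variance_ratio[1:2]),
    n_network_edges = nrow(edges),
    n_permtest_q05 = sum(permtests$q_value < 0.05),
    n_sibling_q05 = if (!is.null(sib_res)) sum(sib_res$q_value < 0.05) else NULL
  )), "summary.json")

  invisible(list(variance_summary = summ, exclusions = exclusions,
                 retained = retained, regression = regression,
                 permutation_tests = permtests, fluctuation = fluct,
                 meanvar_correlations = mv, rank_concordance = concordance,
                 pca = pca, correlation = cm, network_edges = edges,
                 group_comparison = groups, sibling_tests = sib_res,
                 run_info = run_info))
}
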