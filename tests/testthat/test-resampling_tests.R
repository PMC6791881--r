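test_that("maximal separation attains the minimum add-one p-value", {
  # constant individuals with distinct baselines: every permutation mixes
  # them and lowers T, so p hits 1/(B+1)
  vals <- as.list(rep(seq(1, 60, length.out = 12), each = 4))
  vals <- lapply(seq_len(12), function(i) rep(seq(1, 60, length.out = 12)[i], 4))
  names(vals) <- sprintf("I%02d", 1:12)
  norm <- obs_from_list(vals)
  norm$value <- norm$frequency_pct
  res <- permutation_test_variance(norm, "s1", n_permutations = 999, seed = 4)
  expect_false(res$exhaustive)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$observed_stat, res$null_mean)
})

test_that("small inputs are enumerated exhaustively and match brute force", {
  norm <- obs_from_list(list(A = c(1.2, 1.9), B = c(3.1, 2.2), C = c(5.3, 4.4)))
  norm$value <- norm$frequency_pct
  expect_message(
    res <- permutation_test_variance(norm, "s1", n_permutations = 999, seed = 1),
    "exhaustively")
  expect_true(res$exhaustive)
  expect_identical(res$n_permutations, 90L)  # 6! / (2! 2! 2!)

  # independent oracle: all 720 orderings of the 6 values against the fixed
  # grouping; duplicated orderings leave the fraction unchanged
  y <- norm$value
  g <- rep(1:3, each = 2)
  perms <- cytomevar:::all_permutations(6)
  t_stat <- function(v) {
    m <- tapply(v, g, mean); s <- tapply(v, g, var)
    var(m) - mean(s)
  }
  t_all <- apply(perms, 1, function(ix) t_stat(y[ix]))
  t_obs <- t_stat(y)
  expect_equal(res$observed_stat, t_obs)
  expect_equal(res$p_value, mean(t_all >= t_obs - 1e-12))
})

test_that("permutation p-values are reproducible and label invariant", {
  set.seed(31)
  vals <- lapply(1:8, function(i) rnorm(4, mean = i))
  names(vals) <- sprintf("I%d", 1:8)
  norm <- obs_from_list(vals)
  norm$value <- norm$frequency_pct

  r1 <- permutation_test_variance(norm, "s1", 199, seed = 5)
  r2 <- permutation_test_variance(norm, "s1", 199, seed = 5)
  expect_identical(r1, r2)

  # relabeling individuals and reordering visits changes nothing
  relab <- norm
  relab$individual_id <- chartr("12345678", "87654321", relab$individual_id)
  relab <- relab[rev(seq_len(nrow(relab))), ]
  r3 <- permutation_test_variance(relab, "s1", 199, seed = 5)
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(r3$observed_stat, r1$observed_stat)

  expect_error(permutation_test_variance(norm, "s1", n_permutations = 50),
               ">= 99")
})

test_that("identical siblings give zero distance and the minimal p-value", {
  base <- seq(2, 20, length.out = 8)
  sib <- data.frame(
    family_id = rep(sprintf("F%d", 1:8), each = 2),
    individual_id = sprintf("F%d_S%d", rep(1:8, each = 2), rep(1:2, 8)),
    sex = "F", age_years = 30, subset_id = "s1",
    frequency_pct = rep(base, each = 2), stringsAsFactors = FALSE)
  set.seed(12)
  ref <- obs_from_list(setNames(as.list(runif(20, 1, 30)), sprintf("R%02d", 1:20)))
  res <- sibling_concordance_test(validate_siblings(sib), ref, "s1",
                                  n_resamples = 199, seed = 3)
  expect_equal(res$observed_mean_distance, 0)
  expect_equal(res$p_value, 1 / 200)
  expect_identical(res$n_pairs, 8L)

  # deterministic given seed
  res2 <- sibling_concordance_test(validate_siblings(sib), ref, "s1",
                                   n_resamples = 199, seed = 3)
  expect_identical(res, res2)
})

test_that("families with extra siblings contribute all pairs; small references error", {
  sib <- data.frame(
    family_id = c(rep("F1", 3), rep("F2", 2), rep("F3", 2)),
    individual_id = c("F1_S1", "F1_S2", "F1_S3", "F2_S1", "F2_S2",
                      "F3_S1", "F3_S2"),
    sex = "M", age_years = 28, subset_id = "s1",
    frequency_pct = c(1, 2, 3, 4, 5, 6, 7), stringsAsFactors = FALSE)
  set.seed(4)
  ref_big <- obs_from_list(setNames(as.list(runif(12, 1, 9)),
                                    sprintf("R%02d", 1:12)))
  res <- sibling_concordance_test(validate_siblings(sib), ref_big, "s1",
                                  n_resamples = 99, seed = 1)
  expect_identical(res$n_pairs, 5L)  # C(3,2) + 1 + 1

  ref_small <- ref_big[ref_big$individual_id %in% sprintf("R%02d", 1:9), ]
  expect_error(sibling_concordance_test(validate_siblings(sib), ref_small,
                                        "s1", 99, seed = 1),
               "reference too small")

  # opting into pair subsampling keeps the disjoint-pair null feasible when
  # there are more sibling pairs than the reference can match
  sib8 <- data.frame(
    family_id = rep(sprintf("G%d", 1:8), each = 2),
    individual_id = sprintf("G%d_S%d", rep(1:8, each = 2), rep(1:2, 8)),
    sex = "M", age_years = 28, subset_id = "s1",
    frequency_pct = seq(1, 16), stringsAsFactors = FALSE)
  expect_error(sibling_concordance_test(validate_siblings(sib8), ref_big,
                                        "s1", 99, seed = 1),
               "reference too small")
  expect_message(
    res_sub <- sibling_concordance_test(validate_siblings(sib8), ref_big,
                                        "s1", 99, seed = 1,
                                        subsample_pairs = TRUE),
    "subsampling")
  expect_identical(res_sub$n_pairs, 6L)  # floor(12 / 2)
})

test_that("batch modes attach BH q-values consistent with fdr_adjust", {
  cfg <- generator_config(n_individuals = 12, n_visits = 3,
                          subsets = subset_spec(c("a", "b"), mu = c(5, 20),
                                                sigma_b = c(0.4, 0.01),
                                                sigma_w = c(0.1, 0.4)),
                          seed = 17)
  norm <- mean_normalize(generate_cohort(cfg)$observations)
  batch <- permutation_test_all(norm, n_permutations = 199, seed = 2)
  expect_identical(nrow(batch), 2L)
  expect_equal(batch$q_value, fdr_adjust(batch$p_value))
  # strong between-structure subset is far more significant
  expect_lt(batch$p_value[batch$subset_id == "a"],
            batch$p_value[batch$subset_id == "b"])
})
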