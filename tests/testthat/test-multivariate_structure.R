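test_that("PCA: rank-1 data, closed-form 2x2 eigenratios, reconstruction", {
  u <- c(1, 2, 3, 4, 5)
  X1 <- outer(u, c(2, -1, 0.5))
  p1 <- pca_individuals(X1, standardize = FALSE)
  expect_equal(p1$explained_variance_ratio[1], 1)

  # 2-feature toy: explained ratios equal covariance eigenvalue ratios
  set.seed(8)
  X2 <- cbind(rnorm(40), rnorm(40))
  X2[, 2] <- X2[, 1] * 0.6 + X2[, 2]
  p2 <- pca_individuals(X2, standardize = FALSE)
  ev <- eigen(cov(X2))$values
  expect_equal(p2$explained_variance_ratio, ev / sum(ev), tolerance = 1e-10)

  # ratios sum to 1 and all components reconstruct the centered matrix
  set.seed(10)
  X3 <- matrix(rnorm(60), nrow = 12)
  p3 <- pca_individuals(X3, standardize = FALSE)
  expect_equal(sum(p3$explained_variance_ratio), 1, tolerance = 1e-10)
  recon <- p3$scores %*% t(p3$loadings)
  expect_equal(unname(recon), sweep(X3, 2, colMeans(X3)), tolerance = 1e-10)
  # sign convention: the largest-|loading| entry of each component is positive
  for (j in seq_len(ncol(p3$loadings))) {
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, j])), j], 0)
  }
  # scores orthogonal across components
  g <- crossprod(p3$scores)
  expect_equal(unname(g - diag(diag(g))), matrix(0, ncol(g), ncol(g)),
               tolerance = 1e-8)

  X3[2, 3] <- NA
  expect_error(pca_individuals(X3), "missing cells")
  expect_silent(pca_individuals(X3, impute_mean = TRUE, standardize = FALSE))
})

test_that("BH adjustment matches hand step-up values and the brute-force oracle", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(c(0.005, 0.04, 0.2)), c(0.015, 0.06, 0.2))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (i in 1:100) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    q <- fdr_adjust(p)
    expect_equal(q, bh_bruteforce(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("correlation matrix matches pairwise Spearman and mirrors q", {
  set.seed(21)
  X <- matrix(rnorm(6 * 4), nrow = 6,
              dimnames = list(NULL, sprintf("f%d", 1:4)))
  cm <- correlation_matrix(X)
  for (i in 1:3) for (j in (i + 1):4) {
    st <- spearman_test(X[, i], X[, j])
    expect_equal(cm$rho[i, j], st$rho)
    expect_equal(cm$p[i, j], st$p_value)
  }
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$q, t(cm$q))
  up <- upper.tri(cm$p)
  expect_equal(cm$q[up], fdr_adjust(cm$p[up]))
  expect_true(all(cm$q[up] >= cm$p[up] - 1e-15))

  # duplicated feature: off-diagonal rho 1 with the smallest q in its row
  Xd <- cbind(X, f5 = X[, 1])
  cmd <- correlation_matrix(Xd)
  expect_equal(cmd$rho["f1", "f5"], 1)
  expect_equal(min(cmd$q, na.rm = TRUE), cmd$q["f1", "f5"])

  # constant feature flagged undefined
  Xc <- cbind(X, f5 = 1)
  cmc <- correlation_matrix(Xc)
  expect_identical(cmc$undefined, "f5")
  expect_true(all(is.na(cmc$rho["f5", ])))
})

test_that("network edge filtering is a deterministic threshold function", {
  set.seed(33)
  X <- matrix(rnorm(12 * 5), nrow = 12,
              dimnames = list(NULL, sprintf("f%d", 1:5)))
  X[, 2] <- X[, 1] + rnorm(12, 0, 0.1)
  cm <- correlation_matrix(X)

  all_edges <- correlation_network(cm, q_threshold = 1.0000001, rho_threshold = 0)
  expect_identical(nrow(all_edges), 10L)  # complete graph on 5 features
  none <- correlation_network(cm, q_threshold = min(cm$q, na.rm = TRUE) / 2)
  expect_identical(nrow(none), 0L)

  # exactly the engineered significant cells survive a strict threshold
  sig <- correlation_network(cm, q_threshold = 0.01, rho_threshold = 0.8)
  expect_identical(nrow(sig), 1L)
  expect_setequal(c(sig$subset_a, sig$subset_b), c("f1", "f2"))
  expect_identical(sig$sign, "positive")
  expect_identical(correlation_network(cm, 0.01, 0.8), sig)  # rerun identity

  # compositional-pair dropping removes same-parent and parent-child edges;
  # f2/f3 share parent f1, f4 is a child of f5, f1 and f5 are root children
  cat <- data.frame(subset_id = sprintf("f%d", 1:5),
                    label = sprintf("f%d", 1:5),
                    parent_gate_id = c("live_pbmc", "f1", "f1", "f5", "live_pbmc"),
                    marker_text = "", stringsAsFactors = FALSE)
  kept <- correlation_network(cm, 1.0000001, 0, catalog = cat,
                              drop_same_parent = TRUE)
  pairs <- paste(kept$subset_a, kept$subset_b)
  expect_false(any(c("f1 f2", "f1 f3", "f2 f3", "f4 f5", "f1 f5") %in% pairs))
  expect_true(all(c("f2 f4", "f3 f4", "f2 f5", "f3 f5", "f1 f4") %in% pairs))
})

test_that("sex comparison uses the exact rank-sum null and Bonferroni clipping", {
  obs <- obs_grid(6, 1, "s1", function(i, j, s) c(1, 2, 3, 4, 5, 6)[i],
                  sex = rep(c("F", "M"), each = 3))
  g <- group_comparison(obs)
  expect_equal(g$p_value, 2 / 20)  # exhaustive C(6,3) enumeration
  expect_equal(g$p_adjusted, min(1, g$p_value * nrow(g)))

  # adjusted p clips at 1 across multiple subsets
  set.seed(55)
  obs4 <- obs_grid(10, 2, sprintf("s%d", 1:4), function(i, j, s) rnorm(1, 50, 5),
                   sex = rep(c("F", "M"), 5))
  g4 <- group_comparison(obs4)
  expect_equal(g4$p_adjusted, pmin(1, g4$p_value * 4))
  expect_true(any(g4$p_adjusted == 1))

  one_sex <- obs
  one_sex$sex <- "F"
  expect_error(group_comparison(one_sex), "2 non-empty groups")
})
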