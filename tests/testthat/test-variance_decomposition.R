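test_that("mean-normalization centers every subset at 1 and is scale invariant", {
  obs <- obs_from_list(list(A = c(5, 5), B = 5))
  expect_equal(mean_normalize(obs)$value, rep(1, 3))

  obs2 <- obs_from_list(list(A = c(1, 2), B = 3))
  norm2 <- mean_normalize(obs2)
  expect_equal(norm2$value, c(0.5, 1, 1.5))
  expect_equal(var(norm2$value), 0.25)

  # identical shapes at means 0.1 and 50 give identical normalized variances
  shape <- c(0.8, 1.1, 0.9, 1.2, 1.0, 1.0)
  obs3 <- rbind(obs_from_list(list(A = 0.1 * shape[1:3], B = 0.1 * shape[4:6]),
                              subset_id = "small"),
                obs_from_list(list(A = 50 * shape[1:3], B = 50 * shape[4:6]),
                              subset_id = "large"))
  n3 <- mean_normalize(obs3)
  expect_equal(var(n3$value[n3$subset_id == "small"]),
               var(n3$value[n3$subset_id == "large"]))

  zero <- obs_from_list(list(A = c(0, 0), B = 0))
  expect_error(mean_normalize(zero), "zero subset mean.*s1")
})

test_that("descriptive variances match hand computation and ignore visit order", {
  obs <- obs_from_list(list(A = c(1, 3), B = c(5, 7)))
  norm <- obs
  norm$value <- norm$frequency_pct  # treat as already normalized
  d <- descriptive_variances(norm)
  expect_equal(d$var_within, 2)    # (2 + 2) / 2
  expect_equal(d$var_between, 8)   # var(c(2, 6))

  shuffled <- norm[c(2, 1, 4, 3), ]
  expect_equal(descriptive_variances(shuffled), d)

  # a single-visit individual joins the between term but not the within term
  norm1 <- rbind(norm, within(norm[1, ], {
    individual_id <- "C"; frequency_pct <- 10; value <- 10
  }))
  d1 <- descriptive_variances(norm1)
  expect_equal(d1$var_within, 2)
  expect_equal(d1$var_between, var(c(2, 6, 10)))

  # pure between: constant individuals, distinct baselines
  obs_pb <- obs_from_list(list(A = c(1, 1), B = c(2, 2), C = c(5, 5)))
  obs_pb$value <- obs_pb$frequency_pct
  dpb <- descriptive_variances(obs_pb)
  expect_equal(dpb$var_within, 0)
  expect_gt(dpb$var_between, 0)

  # pooled alternative definition
  dp <- descriptive_variances(norm, between = "pooled")
  expect_equal(dp$var_between, var(c(1, 3, 5, 7)))
})

test_that("balanced ANOVA closed form matches the hand example", {
  vals <- c(1, 3, 5, 7)
  ids <- c("A", "A", "B", "B")
  cf <- anova_variance_components(vals, ids)
  expect_equal(cf$sigma2_w, 2)
  expect_equal(cf$sigma2_b, 7)  # (MSB - MSW) / n = (16 - 2) / 2
  expect_equal(cf$prop_within, 2 / 9)
  expect_error(anova_variance_components(c(1, 2, 3), c("A", "A", "B")),
               "balanced")
})

test_that("REML components: degenerate data, truncation at 0, recovery", {
  flat <- list(sigma2_b = 0, sigma2_w = 0, prop_within = NA_real_,
               degenerate = TRUE)
  expect_equal(fit_variance_components(rep(2, 9), rep(c("A", "B", "C"), 3)),
               flat)

  # within-dominated data drives the between component to the 0 boundary
  set.seed(7)
  y <- rnorm(40)
  ids <- rep(sprintf("I%d", 1:10), each = 4)
  fit <- fit_variance_components(y, ids)
  expect_gte(fit$sigma2_b, 0)
  expect_true(fit$prop_within >= 0 && fit$prop_within <= 1)

  # generator truth at large n: raw-scale components have closed forms
  cfg <- tiny_config(n_individuals = 500, n_visits = 4, seed = 21,
                     subsets = subset_spec("s1", mu = 10, sigma_b = 0.3,
                                           sigma_w = 0.3))
  coh <- generate_cohort(cfg)
  fit2 <- fit_variance_components(coh$observations$frequency_pct,
                                  coh$observations$individual_id)
  s2b_true <- 10^2 * exp(0.3^2) * (exp(0.3^2) - 1)
  s2w_true <- (10 * 0.3)^2
  prop_true <- s2w_true / (s2b_true + s2w_true)
  expect_lt(abs(fit2$prop_within - prop_true), 0.05)
  expect_error(fit_variance_components(1:4, c("A", "A", "B", "B")),
               ">= 3 individuals")
})

test_that("Tukey far-out fence flags engineered outlier subsets only", {
  base <- data.frame(subset_id = sprintf("s%d", 1:5),
                     var_technical = c(1, 1, 1, 1, 100),
                     var_between = 1, stringsAsFactors = FALSE)
  flags <- detect_outlier_subsets(base, "var_technical")
  expect_identical(flags$subset_id[flags$flagged], "s5")

  same <- base
  same$var_technical <- 2
  expect_false(any(detect_outlier_subsets(same, "var_technical")$flagged))

  # generator-driven: one subset's replicate noise inflated ~50x
  cfg <- generator_config(
    subsets = subset_spec(sprintf("s%d", 1:8), mu = 10, sigma_b = 0.3,
                          sigma_w = 0.2),
    technical_cv = 0.05, n_replicate_runs = 30, seed = 13)
  reps <- generate_replicates(cfg)$replicates
  noisy <- reps$subset_id == "s4"
  set.seed(99)
  reps$frequency_pct[noisy] <- reps$frequency_pct[noisy] *
    exp(rnorm(sum(noisy), 0, sqrt(log(1 + 2.5^2))))
  reps$frequency_pct <- pmin(reps$frequency_pct, 100)
  obs <- generate_cohort(cfg)$observations
  summ <- variance_summary(obs, validate_replicates(reps))
  out <- detect_outlier_subsets(summ, "var_technical")
  expect_true(out$flagged[out$subset_id == "s4"])
  expect_identical(sum(out$flagged), 1L)
})

test_that("within-on-between regression matches the normal-equations oracle", {
  # perfect proportionality
  s <- data.frame(subset_id = sprintf("s%d", 1:6),
                  var_between = c(1, 2, 3, 4, 5, 6), stringsAsFactors = FALSE)
  s$var_within <- 0.5 * s$var_between
  s$var_technical <- 0.1
  fit <- regress_within_on_between(s)
  expect_equal(fit$adjusted_r_squared, 1)
  expect_equal(fit$slope, 0.5)

  # 5-point toy vs closed-form OLS
  toy <- data.frame(subset_id = sprintf("s%d", 1:5),
                    var_between = c(0.2, 0.5, 1.1, 1.7, 2.3),
                    var_within = c(0.15, 0.2, 0.8, 0.7, 1.6),
                    var_technical = c(0.01, 0.05, 0.02, 0.08, 0.03),
                    stringsAsFactors = FALSE)
  X <- cbind(1, toy$var_between)
  beta <- solve(t(X) %*% X, t(X) %*% toy$var_within)
  fit_toy <- regress_within_on_between(toy)
  expect_equal(fit_toy$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit_toy$slope, beta[2], tolerance = 1e-10)

  # adjusted fit uses the technical covariate
  fit_adj <- regress_within_on_between(toy, adjust_technical = TRUE)
  expect_identical(fit_adj$covariates, c("var_between", "var_technical"))

  col <- toy
  col$var_technical <- 2 * col$var_between
  expect_error(regress_within_on_between(col, adjust_technical = TRUE),
               "collinear")
})

test_that("normalized variance outputs are invariant to positive rescaling", {
  obs <- obs_grid(6, 3, c("a", "b"), function(i, j, s) 5 * s + i + 0.3 * j)
  s1 <- variance_summary(obs)
  obs2 <- obs
  obs2$frequency_pct[obs2$subset_id == "a"] <- 7.3 *
    obs2$frequency_pct[obs2$subset_id == "a"]
  s2 <- variance_summary(obs2)
  for (f in c("var_between", "var_within", "sigma2_b", "sigma2_w", "prop_within")) {
    expect_equal(s2[[f]], s1[[f]], tolerance = 1e-9)
  }
})
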