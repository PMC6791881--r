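#' Mean-normalize frequencies per subset
#'
#' Divides every observation by its subset's grand mean over all retained
#' observations, so that every subset's normalized mean is 1 and variances
#' become comparable across subsets whose population sizes differ by orders
#' of magnitude. Works on observation tables and replicate tables alike (any
#' table with `subset_id` and `frequency_pct`).
#'
#' @param tab table with `subset_id` and `frequency_pct` columns.
#' @return the table with an added `value` column (normalized frequency).
#' @export
mean_normalize <- function(tab) {
  stopifnot(all(c("subset_id", "frequency_pct") %in% names(tab)))
  counts <- table(tab$subset_id)
  if (any(counts < 2L)) {
    validation_error("mean_normalize: subset(s) with fewer than 2 observations: ",
                     paste(names(counts)[counts < 2L], collapse = ", "))
  }
  means <- tapply(tab$frequency_pct, tab$subset_id, mean)
  zero <- names(means)[means == 0]
  if (length(zero) > 0L) {
    validation_error("mean_normalize: zero subset mean for: ",
                     paste(zero, collapse = ", "))
  }
  tab$value <- tab$frequency_pct / as.numeric(means[tab$subset_id])
  tab
}

# between/within descriptive variances for one subset's normalized values
descriptive_one <- function(value, individual_id,
                            between = c("individual_means", "pooled")) {
  between <- match.arg(between)
  by_ind <- split(value, individual_id)
  ind_means <- vapply(by_ind, mean, numeric(1))
  ind_vars <- vapply(by_ind, sample_var, numeric(1))
  eligible <- !is.na(ind_vars)
  var_between <- if (between == "pooled") sample_var(value) else sample_var(ind_means)
  var_within <- if (any(eligible)) mean(ind_vars[eligible]) else NA_real_
  list(var_between = var_between, var_within = var_within,
       n_individuals = length(by_ind),
       mean_visits = mean(lengths(by_ind)))
}

#' Descriptive between/within/technical variances per subset
#'
#' On mean-normalized values: the between-individual variance is the sample
#' variance (n-1 denominator) across individuals of the per-individual means;
#' the within-individual variance is the unweighted mean of the
#' per-individual sample variances across visits (individuals with a single
#' visit contribute to the between term only); the technical variance is the
#' sample variance across staining runs of the normalized control values.
#'
#' @param norm mean-normalized observation table (from [mean_normalize()]).
#' @param reps_norm optional mean-normalized replicate table.
#' @param between `"individual_means"` (default) or `"pooled"` — whether the
#'   between term is the variance of per-individual means or of all pooled
#'   observations.
#' @return data frame: `subset_id, mean_raw, var_between, var_within,
#'   var_technical, n_individuals, mean_visits_per_individual`.
#' @export
descriptive_variances <- function(norm, reps_norm = NULL,
                                  between = c("individual_means", "pooled")) {
  between <- match.arg(between)
  stopifnot("value" %in% names(norm))
  if (length(unique(norm$individual_id)) < 2L) {
    validation_error("descriptive_variances: need at least 2 individuals")
  }
  tech <- if (!is.null(reps_norm)) {
    vapply(split(reps_norm$value, reps_norm$subset_id), sample_var, numeric(1))
  } else NULL
  out <- lapply(split(norm, norm$subset_id), function(d) {
    dsc <- descriptive_one(d$value, d$individual_id, between = between)
    data.frame(
      subset_id = d$subset_id[1L],
      mean_raw = mean(d$frequency_pct),
      var_between = dsc$var_between,
      var_within = dsc$var_within,
      var_technical = if (!is.null(tech) && d$subset_id[1L] %in% names(tech))
        tech[[d$subset_id[1L]]] else NA_real_,
      n_individuals = dsc$n_individuals,
      mean_visits_per_individual = dsc$mean_visits,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' One-way random-intercept variance components (REML)
#'
#' Fits `y_ij = mu + b_i + e_ij` with `b_i ~ N(0, sigma2_b)` and
#' `e_ij ~ N(0, sigma2_w)` by restricted maximum likelihood (lme4). Component
#' estimates are bounded at zero; `prop_within = sigma2_w / (sigma2_b +
#' sigma2_w)` is `NA` (flagged degenerate) when both components vanish.
#'
#' @param values numeric response (e.g. mean-normalized or log frequencies).
#' @param individual_id grouping factor, same length as `values`.
#' @return list: `sigma2_b`, `sigma2_w`, `prop_within`, `degenerate`.
#' @export
fit_variance_components <- function(values, individual_id) {
  keep <- !is.na(values)
  values <- values[keep]
  individual_id <- individual_id[keep]
  if (length(unique(individual_id)) < 3L) {
    validation_error("fit_variance_components: need >= 3 individuals")
  }
  if (!any(table(individual_id) >= 2L)) {
    validation_error("fit_variance_components: no individual has >= 2 visits")
  }
  if (stats::sd(values) == 0) {
    return(list(sigma2_b = 0, sigma2_w = 0, prop_within = NA_real_,
                degenerate = TRUE))
  }
  d <- data.frame(y = values, id = factor(individual_id))
  fit <- suppressMessages(lme4::lmer(
    y ~ 1 + (1 | id), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE,
                                optCtrl = list(xtol_abs = 1e-12,
                                               ftol_abs = 1e-14))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_b <- max(vc$vcov[vc$grp == "id"], 0)
  sigma2_w <- max(vc$vcov[vc$grp == "Residual"], 0)
  total <- sigma2_b + sigma2_w
  list(sigma2_b = sigma2_b, sigma2_w = sigma2_w,
       prop_within = if (total > 0) sigma2_w / total else NA_real_,
       degenerate = total == 0)
}

#' Closed-form balanced one-way ANOVA variance components
#'
#' Method-of-moments estimator for a balanced design with `k` individuals and
#' `n` visits each: `sigma2_w = MSW`, `sigma2_b = (MSB - MSW) / n`, truncated
#' at zero. Used as the independent check of the REML fit on balanced data.
#'
#' @inheritParams fit_variance_components
#' @return list: `sigma2_b`, `sigma2_w`, `prop_within`.
#' @export
anova_variance_components <- function(values, individual_id) {
  by_ind <- split(values, individual_id)
  n_per <- lengths(by_ind)
  if (length(unique(n_per)) != 1L) {
    stop("anova_variance_components requires a balanced design", call. = FALSE)
  }
  n <- n_per[[1L]]
  k <- length(by_ind)
  ind_means <- vapply(by_ind, mean, numeric(1))
  msw <- mean(vapply(by_ind, sample_var, numeric(1)))
  msb <- n * sample_var(ind_means)
  sigma2_w <- msw
  sigma2_b <- max((msb - msw) / n, 0)
  total <- sigma2_b + sigma2_w
  list(sigma2_b = sigma2_b, sigma2_w = sigma2_w,
       prop_within = if (total > 0) sigma2_w / total else NA_real_)
}

#' Per-subset variance summary table
#'
#' Runs mean-normalization, the descriptive between/within/technical
#' estimators and the REML variance-components fit for every subset and
#' returns one row per subset with all `VarianceSummary` fields.
#'
#' @param obs validated observation table.
#' @param reps optional validated replicate table.
#' @inheritParams descriptive_variances
#' @return data frame, one row per subset.
#' @export
variance_summary <- function(obs, reps = NULL,
                             between = c("individual_means", "pooled")) {
  between <- match.arg(between)
  norm <- mean_normalize(obs)
  reps_norm <- if (!is.null(reps)) mean_normalize(reps) else NULL
  dsc <- descriptive_variances(norm, reps_norm, between = between)
  comps <- lapply(split(norm, norm$subset_id), function(d) {
    fit_variance_components(d$value, d$individual_id)
  })
  dsc$sigma2_b <- vapply(dsc$subset_id, function(s) comps[[s]]$sigma2_b, numeric(1))
  dsc$sigma2_w <- vapply(dsc$subset_id, function(s) comps[[s]]$sigma2_w, numeric(1))
  dsc$prop_within <- vapply(dsc$subset_id, function(s) comps[[s]]$prop_within, numeric(1))
  dsc[c("subset_id", "mean_raw", "var_between", "var_within", "var_technical",
        "sigma2_b", "sigma2_w", "prop_within", "n_individuals",
        "mean_visits_per_individual")]
}

#' Flag outlier subsets on a variance field (Tukey far-out fence)
#'
#' Flags subsets whose chosen field exceeds `Q3 + fence * IQR` (quartiles by
#' linear interpolation, type-7), the conservative "far out" fence at the
#' default `fence = 3`. Mirrors the exclusion of subsets whose technical
#' variance is an outlier by a wide margin; flagged subsets are meant to be
#' excluded downstream but retained in reports.
#'
#' @param summaries variance summary data frame.
#' @param field `"var_technical"` (default) or `"var_between"`.
#' @param fence IQR multiplier (default 3).
#' @return data frame: `subset_id`, `value`, `flagged`.
#' @export
detect_outlier_subsets <- function(summaries,
                                   field = c("var_technical", "var_between"),
                                   fence = 3) {
  field <- match.arg(field)
  if (nrow(summaries) < 5L) {
    validation_error("detect_outlier_subsets: need >= 5 subsets")
  }
  v <- summaries[[field]]
  q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  cut <- q[2L] + fence * (q[2L] - q[1L])
  data.frame(subset_id = summaries$subset_id, value = v,
             flagged = !is.na(v) & v > cut, stringsAsFactors = FALSE)
}

#' Regress within-individual on between-individual variance across subsets
#'
#' Ordinary least squares of `var_within` on `var_between` across subsets,
#' optionally adding `var_technical` as a confounding covariate. Reports the
#' slope, intercept, adjusted R-squared and the t statistic / two-sided
#' p-value of the between-variance coefficient.
#'
#' @param summaries variance summary data frame (>= 4 complete subsets).
#' @param adjust_technical include `var_technical` as a covariate.
#' @return list: `slope`, `intercept`, `adjusted_r_squared`, `t_value`,
#'   `p_value`, `covariates`, `n`.
#' @export
regress_within_on_between <- function(summaries, adjust_technical = FALSE) {
  covs <- c("var_between", if (adjust_technical) "var_technical")
  d <- summaries[stats::complete.cases(summaries[c("var_within", covs)]),
                 c("var_within", covs), drop = FALSE]
  if (nrow(d) < 4L) {
    validation_error("regress_within_on_between: need >= 4 subsets with all fields")
  }
  X <- as.matrix(d[covs])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("regress_within_on_between: collinear covariates", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(covs, response = "var_within"), data = d)
  sm <- suppressWarnings(summary(fit))  # degenerate perfect fits are legal inputs
  co <- sm$coefficients
  list(slope = unname(co["var_between", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       adjusted_r_squared = sm$adj.r.squared,
       t_value = unname(co["var_between", "t value"]),
       p_value = unname(co["var_between", "Pr(>|t|)"]),
       covariates = covs, n = nrow(d))
}
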