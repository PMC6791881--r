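#' Individuals-by-subset feature matrix of baselines and/or fluctuations
#'
#' Reshapes the per-(individual, subset) fluctuation summary into the wide
#' matrix PCA and the correlation analyses consume. Baseline features are the
#' per-individual means of z-scores, fluctuation features the per-individual
#' variances of z-scores; `"both"` column-binds the two blocks (column names
#' suffixed `.baseline` / `.fluctuation`).
#'
#' @param summ fluctuation summary from [individual_baseline_fluctuation()].
#' @param what `"baseline"`, `"fluctuation"` or `"both"`.
#' @return numeric matrix, rownames = individual ids.
#' @export
individual_feature_matrix <- function(summ,
                                      what = c("baseline", "fluctuation", "both")) {
  what <- match.arg(what)
  wide <- function(col, suffix) {
    m <- tapply(summ[[col]], list(summ$individual_id, summ$subset_id),
                function(x) x[1L])
    colnames(m) <- paste0(colnames(m), suffix)
    m
  }
  switch(what,
    baseline = wide("baseline_z_mean", ""),
    fluctuation = wide("fluctuation_z_var", ""),
    both = cbind(wide("baseline_z_mean", ".baseline"),
                 wide("fluctuation_z_var", ".fluctuation"))
  )
}

#' PCA of individuals on immune-profile features
#'
#' Columns are centered (and unit-scaled when `standardize`, the default —
#' baseline and fluctuation features live on different scales) and
#' decomposed by singular values. Explained variance ratios are the squared
#' singular values over their sum; each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param features individuals x features numeric matrix, no missing cells
#'   unless `impute_mean`.
#' @param standardize unit-scale columns (default TRUE).
#' @param impute_mean replace missing cells by their column mean.
#' @return list: `scores` (individuals x components), `loadings`
#'   (features x components), `explained_variance_ratio`.
#' @export
pca_individuals <- function(features, standardize = TRUE, impute_mean = FALSE) {
  X <- as.matrix(features)
  if (nrow(X) < 3L || ncol(X) < 2L) {
    validation_error("pca_individuals: need >= 3 individuals and >= 2 features")
  }
  if (anyNA(X)) {
    if (!impute_mean) {
      bad <- which(is.na(X), arr.ind = TRUE)
      validation_error("pca_individuals: missing cells (set impute_mean = TRUE): ",
                       paste(utils::head(paste0("[", rownames(X)[bad[, 1L]], ", ",
                                                colnames(X)[bad[, 2L]], "]"), 5L),
                             collapse = " "))
    }
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      X[nas, j] <- mean(X[!nas, j])
    }
  }
  X <- scale(X, center = TRUE, scale = standardize)
  if (standardize && any(!is.finite(X))) {
    validation_error("pca_individuals: constant feature column cannot be scaled")
  }
  sv <- svd(X)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncomp)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(d, ncomp)
  dimnames(scores) <- list(rownames(features), paste0("PC", seq_len(ncomp)))
  dimnames(V) <- list(colnames(features), paste0("PC", seq_len(ncomp)))
  evr <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, loadings = V,
       explained_variance_ratio = evr[seq_len(ncomp)])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1 and
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in \[0, 1\] (`NA` passed through).
#' @return q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    validation_error("fdr_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pairwise Spearman correlation matrix with FDR control
#'
#' Spearman rho over individuals for every pair of features (average ranks
#' for ties), two-sided p-values by the package's Spearman rule (exact
#' enumeration below 10 individuals, t approximation otherwise), and BH
#' q-values computed over the strict upper triangle only, then mirrored.
#' Constant features get `NA` rows/columns and are reported in `undefined`.
#'
#' @param features individuals x features numeric matrix (>= 5 rows).
#' @return list: `rho`, `p`, `q` (symmetric matrices, unit/`NA` diagonal),
#'   `n` (individuals per cell), `undefined` (constant feature names).
#' @export
correlation_matrix <- function(features) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 5L) validation_error("correlation_matrix: need >= 5 individuals")
  k <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  undef <- colnames(X)[is.na(sds) | sds == 0]
  ranks <- apply(X, 2L, rank)
  rho <- suppressWarnings(stats::cor(ranks))
  rho[is.na(sds) | sds == 0, ] <- NA_real_
  rho[, is.na(sds) | sds == 0] <- NA_real_
  diag(rho) <- ifelse(is.na(sds) | sds == 0, NA_real_, 1)
  if (n < 10L) {
    p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (!is.na(rho[i, j])) {
          p[i, j] <- p[j, i] <- spearman_test(X[, i], X[, j])$p_value
        }
      }
    }
  } else {
    r2 <- pmin(rho^2, 1 - 1e-15)
    tval <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  diag(p) <- NA_real_
  up <- upper.tri(p)
  q <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  q[up] <- fdr_adjust(p[up])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(rho = rho, p = p, q = q, n = n, undefined = undef)
}

#' Edge list of the significant-correlation network
#'
#' Keeps feature pairs with `q < q_threshold` and `|rho| >= rho_threshold`.
#' When a catalog is supplied and `drop_same_parent` is set, pairs that share
#' a parent gate or stand in a direct parent-child relation are dropped:
#' their (typically negative) correlations are compositional artifacts of
#' frequencies summing within a gate, not biology.
#'
#' @param cm result of [correlation_matrix()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param rho_threshold minimum |rho| (default 0).
#' @param catalog optional subset catalog for compositional-pair dropping.
#' @param drop_same_parent drop same-parent and parent-child pairs.
#' @return data frame: `subset_a, subset_b, rho, sign, q`.
#' @export
correlation_network <- function(cm, q_threshold = 0.05, rho_threshold = 0,
                                catalog = NULL, drop_same_parent = FALSE) {
  rho <- cm$rho
  q <- cm$q
  ids <- colnames(rho)
  up <- which(upper.tri(rho), arr.ind = TRUE)
  keep <- !is.na(q[up]) & q[up] < q_threshold &
    !is.na(rho[up]) & abs(rho[up]) >= rho_threshold
  edges <- data.frame(
    subset_a = ids[up[keep, 1L]],
    subset_b = ids[up[keep, 2L]],
    rho = rho[up][keep],
    sign = ifelse(rho[up][keep] >= 0, "positive", "negative"),
    q = q[up][keep],
    stringsAsFactors = FALSE
  )
  if (drop_same_parent && !is.null(catalog) && nrow(edges) > 0L) {
    parent <- stats::setNames(catalog$parent_gate_id, catalog$subset_id)
    pa <- parent[edges$subset_a]
    pb <- parent[edges$subset_b]
    compositional <- (!is.na(pa) & !is.na(pb) & pa == pb) |
      (!is.na(pa) & pa == edges$subset_b) |
      (!is.na(pb) & pb == edges$subset_a)
    edges <- edges[!compositional, , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Per-subset group comparison (sex) with Bonferroni correction
#'
#' Collapses each individual to their mean frequency over visits, then runs a
#' two-sided Wilcoxon rank-sum test per subset between the two groups (exact
#' null when the combined sample is <= 20 without ties, normal approximation
#' with tie/continuity correction otherwise). Adjusted p = `min(1, p * m)`
#' over the m subsets tested.
#'
#' @param obs validated observation table.
#' @param group_field grouping column (currently `"sex"`); individuals with
#'   level `"unknown"` are dropped.
#' @return data frame: `subset_id, statistic, p_value, p_adjusted,
#'   n_group1, n_group2` (+ group labels as attributes).
#' @export
group_comparison <- function(obs, group_field = "sex") {
  stopifnot(group_field %in% names(obs))
  d <- obs[obs[[group_field]] != "unknown", , drop = FALSE]
  key <- interaction(d$individual_id, d$subset_id, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(d, key), function(x) {
    data.frame(individual_id = x$individual_id[1L], subset_id = x$subset_id[1L],
               group = x[[group_field]][1L], value = mean(x$frequency_pct),
               stringsAsFactors = FALSE)
  }))
  groups <- sort(unique(agg$group))
  if (length(groups) != 2L) {
    stop("group_comparison: need exactly 2 non-empty groups, got ",
         length(groups), call. = FALSE)
  }
  if (any(table(agg$group[!duplicated(agg$individual_id)]) < 2L)) {
    validation_error("group_comparison: both groups need >= 2 individuals")
  }
  res <- lapply(split(agg, agg$subset_id), function(s) {
    x <- s$value[s$group == groups[1L]]
    y <- s$value[s$group == groups[2L]]
    exact <- (length(x) + length(y)) <= 20L &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    data.frame(subset_id = s$subset_id[1L], statistic = unname(wt$statistic),
               p_value = wt$p.value, n_group1 = length(x),
               n_group2 = length(y), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  rownames(res) <- NULL
  attr(res, "groups") <- groups
  res
}
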