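#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a fixed RNG seed, restoring the caller's stream
#'
#' All stochastic operations in the package take an explicit `seed` and go
#' through this helper, so calling them never perturbs the global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Sample variance with the n-1 denominator; NA when fewer than 2 values.
sample_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::var(x)
}

# Group means and sample variances via rowsum (fast path used by the
# permutation loop). `g` must be an integer grouping in 1..k.
group_moments <- function(y, g, k) {
  n <- tabulate(g, nbins = k)
  s1 <- rowsum(y, g, reorder = TRUE)[, 1L]
  s2 <- rowsum(y * y, g, reorder = TRUE)[, 1L]
  m <- s1 / n
  v <- ifelse(n >= 2L, (s2 - n * m^2) / (n - 1L), NA_real_)
  # guard tiny negative values from cancellation
  v <- ifelse(!is.na(v) & v < 0, 0, v)
  list(n = n, mean = m, var = v)
}

#' All permutations of 1..n (iterative Steinhaus-Johnson-Trotter-free builder)
#' @return matrix with n! rows, each a permutation.
#' @keywords internal
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 10L)
  perms <- matrix(1L, nrow = 1L, ncol = 1L)
  for (m in seq_len(n)[-1L]) {
    prev <- perms
    out <- matrix(0L, nrow = nrow(prev) * m, ncol = m)
    row <- 0L
    for (pos in seq_len(m)) {
      idx <- seq_len(nrow(prev)) + row
      if (pos == 1L) {
        out[idx, ] <- cbind(m, prev)
      } else if (pos == m) {
        out[idx, ] <- cbind(prev, m)
      } else {
        out[idx, ] <- cbind(prev[, seq_len(pos - 1L), drop = FALSE], m,
                            prev[, pos:(m - 1L), drop = FALSE])
      }
      row <- row + nrow(prev)
    }
    perms <- out
  }
  perms
}

#' Spearman rank correlation with the package's p-value rule
#'
#' rho is the Pearson correlation of average ranks (so ties are handled).
#' Two-sided p-value: exact enumeration over all rank permutations for
#' n < 10, the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' otherwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearman_test needs at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "undefined"))
  }
  rho <- stats::cor(rx, ry)
  if (n < 10L) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # rho for every permutation of y's ranks against fixed x ranks
    rho_all <- (matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tval <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# stop() with a consistent prefix for validation failures
validation_error <- function(...) {
  stop(paste0("validation error: ", ...), call. = FALSE)
}
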