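# in-code fixture builders shared across test files

# long observation table from a named list: values[[individual]] = visit values
obs_from_list <- function(values, subset_id = "s1", sex = "M") {
  do.call(rbind, lapply(names(values), function(id) {
    v <- values[[id]]
    data.frame(individual_id = id, visit_index = seq_along(v),
               collection_date = NA_character_, sex = sex, age_years = 25,
               subset_id = subset_id, frequency_pct = v,
               stringsAsFactors = FALSE)
  }))
}

# complete grid of individuals x visits for several subsets, values supplied
# as a function(individual index, visit index, subset index)
obs_grid <- function(n_ind, n_visit, subset_ids, value_fun,
                     sex = rep(c("M", "F"), length.out = n_ind)) {
  g <- expand.grid(i = seq_len(n_ind), j = seq_len(n_visit),
                   s = seq_along(subset_ids))
  data.frame(individual_id = sprintf("I%02d", g$i), visit_index = g$j,
             collection_date = NA_character_, sex = sex[g$i], age_years = 25,
             subset_id = subset_ids[g$s],
             frequency_pct = mapply(value_fun, g$i, g$j, g$s),
             stringsAsFactors = FALSE)
}

# tiny generator config: one or two subsets, quick to draw
tiny_config <- function(..., subsets = subset_spec("s1", mu = 10,
                                                   sigma_b = 0.4,
                                                   sigma_w = 0.25)) {
  generator_config(subsets = subsets, ...)
}

# independent brute-force BH step-up (oracle for fdr_adjust)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
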