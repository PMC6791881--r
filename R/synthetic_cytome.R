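#' Per-subset generative parameters
#'
#' Builds the subset-specification table of the hierarchical generator. Each
#' subset has a lognormal baseline distribution across individuals:
#' individual `i` carries a stable log-scale baseline `b_is ~ N(0,
#' sigma_b^2)`, so steady-state levels `mu_s * exp(b_is)` are positive,
#' right-skewed and span orders of magnitude across subsets. At visit `j` the
#' observed frequency is
#' `y_ijs = clamp(mu_s * (exp(b_is) + delta_ijs), 0, 100)` with visit noise
#' `delta_ijs ~ N(0, (sigma_w * exp(kappa * b_is))^2)` — mean-scaled so
#' `sigma_w` is the visit-level SD relative to the population mean.
#'
#' `kappa = 0` gives a stable subset whose temporal fluctuation is
#' independent of the individual's level (an exact independence null for the
#' mean-variance coupling analysis); `kappa > 0` makes high-baseline
#' individuals fluctuate more — the environmentally responsive signature in
#' which upward excursions drag the mean up and couple per-individual mean
#' and variance. Coupling enters only through the visit-noise SD, never the
#' baseline.
#'
#' @param subset_id character keys.
#' @param mu population mean frequency, percent of parent gate, in (0, 100).
#' @param sigma_b between-individual SD of the log-scale baseline (>= 0).
#' @param sigma_w within-individual (visit-level) SD on the log scale (>= 0).
#' @param kappa mean-variance coupling coefficient (>= 0).
#' @return data frame with one row per subset.
#' @export
subset_spec <- function(subset_id, mu, sigma_b, sigma_w, kappa = 0) {
  df <- data.frame(subset_id = subset_id, mu = mu, sigma_b = sigma_b,
                   sigma_w = sigma_w, kappa = kappa, stringsAsFactors = FALSE)
  if (anyDuplicated(df$subset_id)) validation_error("subset_spec: duplicate subset_id")
  if (any(df$mu <= 0 | df$mu >= 100)) validation_error("subset_spec: mu must be in (0, 100)")
  if (any(df$sigma_b < 0 | df$sigma_w < 0)) validation_error("subset_spec: SDs must be >= 0")
  if (any(df$kappa < 0)) validation_error("subset_spec: kappa must be >= 0")
  df
}

#' Default 35-subset specification mirroring the synthetic study panel
#'
#' Population means span three orders of magnitude (0.08% iNKT to 80%
#' classical monocytes). Between-individual spread and visit-level spread are
#' proportional across subsets (`sigma_w = 0.6 * sigma_b`), the structure in
#' which subsets that vary a lot between people also fluctuate a lot within
#' them. Exposure-driven subsets (plasmablasts, EMRA/TEMRA T cells, gamma
#' delta T, inflammatory monocytes, B1) carry `kappa = 1` so their
#' per-individual mean and variance are coupled; memory/naive/regulatory
#' subsets carry `kappa = 0`.
#'
#' @return subset specification data frame (35 rows).
#' @export
default_subset_specs <- function() {
  responsive <- c("plasmablast", "plasmablast_iga", "cd4_emra", "cd8_emra",
                  "gd_t", "mono_inflammatory", "b1", "plasmablast_igg_syn")
  mu <- c(
    t_cell = 60, cd4 = 55, cd8 = 30, gd_t = 4, nkt = 5, inkt = 0.08,
    cd4_naive = 45, cd4_memory = 40, cd4_emra = 3, treg = 6, ntreg = 70,
    itreg = 30, cd39_treg = 40, cd39_ntreg = 45, cd39_itreg = 25,
    cd8_naive = 40, cd8_memory = 30, cd8_emra = 15, b_cell = 10,
    b_naive = 60, b_memory = 25, b_immature = 5, b1 = 2, plasmablast = 1.5,
    plasmablast_iga = 20, nk_cell = 12, monocyte = 20, mono_classical = 80,
    mono_inflammatory = 8, mono_patrolling = 5, dc = 1.5, mdc = 60, pdc = 30,
    plasmablast_igg_syn = 10, nkt_cd8_syn = 15
  )
  sigma_b <- c(
    t_cell = 0.10, cd4 = 0.12, cd8 = 0.15, gd_t = 0.55, nkt = 0.40,
    inkt = 0.60, cd4_naive = 0.18, cd4_memory = 0.14, cd4_emra = 0.60,
    treg = 0.20, ntreg = 0.12, itreg = 0.22, cd39_treg = 0.25,
    cd39_ntreg = 0.22, cd39_itreg = 0.28, cd8_naive = 0.20,
    cd8_memory = 0.16, cd8_emra = 0.50, b_cell = 0.25, b_naive = 0.15,
    b_memory = 0.18, b_immature = 0.35, b1 = 0.45, plasmablast = 0.70,
    plasmablast_iga = 0.40, nk_cell = 0.30, monocyte = 0.22,
    mono_classical = 0.08, mono_inflammatory = 0.50, mono_patrolling = 0.38,
    dc = 0.30, mdc = 0.14, pdc = 0.26, plasmablast_igg_syn = 0.45,
    nkt_cd8_syn = 0.32
  )
  ids <- names(mu)
  subset_spec(
    subset_id = ids,
    mu = unname(mu),
    sigma_b = unname(sigma_b),
    sigma_w = unname(0.6 * sigma_b),
    kappa = ifelse(ids %in% responsive, 1, 0)
  )
}

#' Configuration of the synthetic hierarchical cohort generator
#'
#' Defaults mirror the synthetic study design: 43 individuals bled quarterly
#' for a year (4 visits), 35 subsets, a control sample stained with each of
#' 40 runs (5% technical CV), and 37 two-sibling families sharing half of the
#' between-individual baseline variance.
#'
#' @param n_individuals longitudinal cohort size.
#' @param n_visits visits per individual.
#' @param subsets subset specification data frame (see [subset_spec()]).
#' @param technical_cv coefficient of variation of the multiplicative
#'   run-to-run technical noise (>= 0).
#' @param n_replicate_runs number of staining runs of the control sample.
#' @param n_families number of sibling families.
#' @param n_siblings_per_family siblings per family (>= 2).
#' @param sibling_shared_fraction fraction of between-individual baseline
#'   variance shared within a family, in \[0, 1\].
#' @param seed master seed; the cohort, replicate and sibling tables draw from
#'   separate streams derived by fixed offsets (+0, +1, +2) so generating one
#'   table never perturbs another.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 43L, n_visits = 4L,
                             subsets = default_subset_specs(),
                             technical_cv = 0.05, n_replicate_runs = 40L,
                             n_families = 37L, n_siblings_per_family = 2L,
                             sibling_shared_fraction = 0.5, seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_visits = as.integer(n_visits),
    subsets = subsets, technical_cv = technical_cv,
    n_replicate_runs = as.integer(n_replicate_runs),
    n_families = as.integer(n_families),
    n_siblings_per_family = as.integer(n_siblings_per_family),
    sibling_shared_fraction = sibling_shared_fraction, seed = as.integer(seed)
  )
  if (cfg$n_individuals < 1L || cfg$n_visits < 1L || cfg$n_replicate_runs < 1L ||
      cfg$n_families < 1L || cfg$n_siblings_per_family < 2L) {
    validation_error("generator_config: counts must be positive (>= 2 siblings/family)")
  }
  if (cfg$technical_cv < 0) validation_error("generator_config: technical_cv must be >= 0")
  if (cfg$sibling_shared_fraction < 0 || cfg$sibling_shared_fraction > 1) {
    validation_error("generator_config: sibling_shared_fraction must be in [0, 1]")
  }
  cfg$subsets <- subset_spec(subsets$subset_id, subsets$mu, subsets$sigma_b,
                             subsets$sigma_w, subsets$kappa)
  structure(cfg, class = "generator_config")
}

#' Read / write a generator configuration as JSON
#' @param path JSON file path.
#' @return `generator_config` (read) or `path` invisibly (write).
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$subsets <- as.data.frame(x$subsets, stringsAsFactors = FALSE)
  do.call(generator_config, x)
}

#' @rdname read_generator_config
#' @param config a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

clamp_pct <- function(y, context) {
  n_clamped <- sum(y > 100 | y < 0)
  if (n_clamped > 0L) {
    message(context, ": clamped ", n_clamped, " value(s) to [0, 100]")
  }
  pmin(pmax(y, 0), 100)
}

# demographics shared by cohort and sibling generators; drawn from the
# active stream
draw_demographics <- function(n, mean_age = 25.8, sd_age = 1.8, p_male = 25 / 43) {
  list(sex = ifelse(stats::runif(n) < p_male, "M", "F"),
       age = round(pmax(stats::rnorm(n, mean_age, sd_age), 18), 1))
}

#' Generate the longitudinal synthetic cohort
#'
#' Draws the complete `n_individuals x n_visits x n_subsets` grid from the
#' generative model documented in [subset_spec()] and returns both the
#' observation table and a ground-truth manifest (every log-scale baseline
#' `b_is` plus the subset parameters) for parameter-recovery testing.
#' Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list with `observations` (validated observation table) and
#'   `truth` (list: `subsets`, `baselines`, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 0L, {
    n_i <- config$n_individuals
    n_v <- config$n_visits
    sp <- config$subsets
    ind_ids <- sprintf("I%03d", seq_len(n_i))
    demo <- draw_demographics(n_i)
    date0 <- as.Date("2013-06-01") + sample.int(540L, n_i, replace = TRUE)
    rows <- vector("list", nrow(sp))
    base_rows <- vector("list", nrow(sp))
    for (s in seq_len(nrow(sp))) {
      b <- stats::rnorm(n_i, 0, sp$sigma_b[s])
      sd_e <- sp$sigma_w[s] * exp(sp$kappa[s] * b)
      e <- stats::rnorm(n_i * n_v, 0, rep(sd_e, each = n_v))
      y <- sp$mu[s] * (exp(rep(b, each = n_v)) + e)
      y <- clamp_pct(y, paste0("generate_cohort[", sp$subset_id[s], "]"))
      idx <- rep(seq_len(n_i), each = n_v)
      vis <- rep(seq_len(n_v), times = n_i)
      rows[[s]] <- data.frame(
        individual_id = ind_ids[idx],
        visit_index = vis,
        collection_date = as.character(date0[idx] + 91L * (vis - 1L)),
        sex = demo$sex[idx],
        age_years = demo$age[idx],
        subset_id = sp$subset_id[s],
        frequency_pct = y,
        stringsAsFactors = FALSE
      )
      base_rows[[s]] <- data.frame(individual_id = ind_ids,
                                   subset_id = sp$subset_id[s],
                                   b = b, stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, rows)
    rownames(obs) <- NULL
    obs <- validate_observations(obs)
    truth <- list(subsets = sp,
                  baselines = do.call(rbind, base_rows),
                  config = unclass(config))
    rownames(truth$baselines) <- NULL
    list(observations = obs, truth = truth)
  })
}

#' Generate the technical-replicate control table
#'
#' One latent control value per subset (a single control donor drawn from the
#' population), re-stained in each of `n_replicate_runs` runs under
#' multiplicative lognormal noise with coefficient of variation
#' `technical_cv` (unit mean, so the latent value is unbiased).
#'
#' @param config a [generator_config()].
#' @return list with `replicates` (validated replicate table) and `truth`
#'   (per-subset latent control values).
#' @export
generate_replicates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 1L, {
    sp <- config$subsets
    n_r <- config$n_replicate_runs
    cv <- config$technical_cv
    control <- sp$mu * exp(stats::rnorm(nrow(sp), 0, sp$sigma_b))
    sdlog <- sqrt(log1p(cv^2))
    mult <- if (cv == 0) {
      rep(1, nrow(sp) * n_r)
    } else {
      exp(stats::rnorm(nrow(sp) * n_r, -sdlog^2 / 2, sdlog))
    }
    y <- rep(control, each = n_r) * mult
    y <- clamp_pct(y, "generate_replicates")
    reps <- data.frame(
      run_id = sprintf("R%03d", rep(seq_len(n_r), times = nrow(sp))),
      subset_id = rep(sp$subset_id, each = n_r),
      frequency_pct = y, stringsAsFactors = FALSE
    )
    list(replicates = validate_replicates(reps),
         truth = data.frame(subset_id = sp$subset_id, control_value = control,
                            stringsAsFactors = FALSE))
  })
}

#' Generate the sibling cohort
#'
#' Per family `f` and subset `s`, a shared log-scale component
#' `g_fs ~ N(0, phi * sigma_b^2)` (`phi` = `sibling_shared_fraction`); each
#' sibling's baseline is `g_fs + u` with `u ~ N(0, (1 - phi) * sigma_b^2)`,
#' so the within-family intraclass correlation of log baselines is `phi`.
#' One observation per sibling per subset, including visit-level noise as in
#' [generate_cohort()].
#'
#' @param config a [generator_config()].
#' @return list with `siblings` (validated sibling table) and `truth`
#'   (per-sibling log baselines).
#' @export
generate_siblings <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 2L, {
    sp <- config$subsets
    n_f <- config$n_families
    k <- config$n_siblings_per_family
    phi <- config$sibling_shared_fraction
    n_s <- n_f * k
    fam_ids <- sprintf("F%03d", rep(seq_len(n_f), each = k))
    sib_ids <- sprintf("F%03d_S%d", rep(seq_len(n_f), each = k),
                       rep(seq_len(k), times = n_f))
    demo <- draw_demographics(n_s, mean_age = 31.8, sd_age = 12.7,
                              p_male = 38 / 80)
    rows <- vector("list", nrow(sp))
    base_rows <- vector("list", nrow(sp))
    for (s in seq_len(nrow(sp))) {
      g <- stats::rnorm(n_f, 0, sqrt(phi) * sp$sigma_b[s])
      u <- stats::rnorm(n_s, 0, sqrt(1 - phi) * sp$sigma_b[s])
      b <- rep(g, each = k) + u
      e <- stats::rnorm(n_s, 0, sp$sigma_w[s] * exp(sp$kappa[s] * b))
      y <- clamp_pct(sp$mu[s] * (exp(b) + e),
                     paste0("generate_siblings[", sp$subset_id[s], "]"))
      rows[[s]] <- data.frame(
        family_id = fam_ids, individual_id = sib_ids, sex = demo$sex,
        age_years = demo$age, subset_id = sp$subset_id[s], frequency_pct = y,
        stringsAsFactors = FALSE
      )
      base_rows[[s]] <- data.frame(family_id = fam_ids, individual_id = sib_ids,
                                   subset_id = sp$subset_id[s], b = b,
                                   stringsAsFactors = FALSE)
    }
    sib <- do.call(rbind, rows)
    rownames(sib) <- NULL
    truth <- do.call(rbind, base_rows)
    rownames(truth) <- NULL
    list(siblings = validate_siblings(sib), truth = truth)
  })
}
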