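#' @name data-model
#' @title Long-format tables for longitudinal immunophenotyping
#'
#' @description
#' All stages consume plain long-format data frames with fixed, documented
#' column schemas:
#'
#' * observations: `individual_id, visit_index, collection_date, sex,
#'   age_years, subset_id, frequency_pct` — one row per individual, visit and
#'   subset; `frequency_pct` is the percent of the parent gate, in \[0, 100\].
#' * replicates: `run_id, subset_id, frequency_pct` — a single control sample
#'   stained alongside each batch, one row per run and subset.
#' * siblings: `family_id, individual_id, sex, age_years, subset_id,
#'   frequency_pct` — one observation per sibling per subset.
#' * catalog: `subset_id, label, parent_gate_id, marker_text` — the gating
#'   hierarchy; `parent_gate_id` resolves to another entry or to the root
#'   marker `"live_pbmc"`.
#'
#' Files are UTF-8 CSV with these headers. Optional fields (only
#' `collection_date`) are serialized as empty strings and read back as `NA`.
NULL

.obs_cols <- c("individual_id", "visit_index", "collection_date", "sex",
               "age_years", "subset_id", "frequency_pct")
.rep_cols <- c("run_id", "subset_id", "frequency_pct")
.sib_cols <- c("family_id", "individual_id", "sex", "age_years",
               "subset_id", "frequency_pct")
.cat_cols <- c("subset_id", "label", "parent_gate_id", "marker_text")

.root_gate <- "live_pbmc"

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("schema error: ", what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[cols]
}

check_frequency <- function(df, mode, what) {
  bad <- which(is.na(df$frequency_pct) | df$frequency_pct < 0 |
                 df$frequency_pct > 100)
  if (length(bad) == 0L) return(df)
  if (mode == "strict") {
    validation_error(what, ": frequency_pct outside [0, 100] at row(s) ",
                     paste(utils::head(bad, 5L), collapse = ", "))
  }
  message("dropping ", length(bad), " row(s) with frequency_pct outside [0, 100]")
  df[-bad, , drop = FALSE]
}

check_unique_key <- function(df, key_cols, mode, what) {
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  dup <- duplicated(key)
  if (!any(dup)) return(df)
  if (mode == "strict") {
    shown <- utils::head(unique(key[dup]), 3L)
    validation_error(what, ": duplicate record(s) for key (",
                     paste(key_cols, collapse = ", "), "): ",
                     paste(gsub("\r", " / ", shown), collapse = "; "))
  }
  message("dropping ", sum(dup), " duplicate row(s)")
  df[!dup, , drop = FALSE]
}

check_sex <- function(df, mode, what) {
  df$sex[is.na(df$sex) | df$sex == ""] <- "unknown"
  bad <- which(!df$sex %in% c("M", "F", "unknown"))
  if (length(bad) == 0L) return(df)
  if (mode == "strict") {
    validation_error(what, ": sex must be M, F or unknown at row(s) ",
                     paste(utils::head(bad, 5L), collapse = ", "))
  }
  df$sex[bad] <- "unknown"
  df
}

#' Validate an observation table
#'
#' @param df data frame with the observation schema columns.
#' @param catalog optional subset catalog; when given, `subset_id` values must
#'   resolve.
#' @param mode `"strict"` (default) rejects any invalid row with an error
#'   naming it; `"lenient"` drops invalid rows with a logged count.
#' @return the validated (possibly filtered) data frame.
#' @export
validate_observations <- function(df, catalog = NULL,
                                  mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  df <- check_columns(df, .obs_cols, "observations")
  df$visit_index <- as.integer(df$visit_index)
  if (any(is.na(df$visit_index) | df$visit_index < 1L)) {
    validation_error("observations: visit_index must be a positive integer")
  }
  if (any(is.na(df$age_years) | df$age_years < 0)) {
    validation_error("observations: age_years must be nonnegative")
  }
  df <- check_sex(df, mode, "observations")
  df <- check_frequency(df, mode, "observations")
  df <- check_unique_key(df, c("individual_id", "visit_index", "subset_id"),
                         mode, "observations")
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(df$subset_id), catalog$subset_id)
    if (length(unknown) > 0L) {
      validation_error("observations: subset_id not in catalog: ",
                       paste(unknown, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Validate a technical-replicate table
#' @inheritParams validate_observations
#' @export
validate_replicates <- function(df, catalog = NULL,
                                mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  df <- check_columns(df, .rep_cols, "replicates")
  df <- check_frequency(df, mode, "replicates")
  df <- check_unique_key(df, c("run_id", "subset_id"), mode, "replicates")
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(df$subset_id), catalog$subset_id)
    if (length(unknown) > 0L) {
      validation_error("replicates: subset_id not in catalog: ",
                       paste(unknown, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Validate a sibling-cohort table
#' @inheritParams validate_observations
#' @export
validate_siblings <- function(df, catalog = NULL,
                              mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  df <- check_columns(df, .sib_cols, "siblings")
  if (any(is.na(df$age_years) | df$age_years < 0)) {
    validation_error("siblings: age_years must be nonnegative")
  }
  df <- check_sex(df, mode, "siblings")
  df <- check_frequency(df, mode, "siblings")
  df <- check_unique_key(df, c("individual_id", "subset_id"), mode, "siblings")
  fam_sizes <- tapply(df$individual_id, df$family_id,
                      function(x) length(unique(x)))
  solo <- names(fam_sizes)[fam_sizes < 2L]
  if (length(solo) > 0L) {
    message("excluding ", length(solo),
            " family(ies) with fewer than 2 members: ",
            paste(solo, collapse = ", "))
    df <- df[!df$family_id %in% solo, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Validate a subset catalog (gating hierarchy)
#'
#' Checks id uniqueness, that every parent resolves to another entry or the
#' root gate, and that the parent relation is acyclic.
#' @param df catalog data frame.
#' @return validated catalog.
#' @export
validate_catalog <- function(df) {
  df <- check_columns(df, .cat_cols, "catalog")
  if (anyDuplicated(df$subset_id)) {
    validation_error("catalog: duplicate subset_id: ",
                     paste(df$subset_id[duplicated(df$subset_id)], collapse = ", "))
  }
  known <- c(df$subset_id, .root_gate)
  bad <- setdiff(unique(df$parent_gate_id), known)
  if (length(bad) > 0L) {
    validation_error("catalog: parent_gate_id does not resolve: ",
                     paste(bad, collapse = ", "))
  }
  # cycle check: walk each node to the root
  parent <- stats::setNames(df$parent_gate_id, df$subset_id)
  for (s in df$subset_id) {
    seen <- character(0)
    cur <- s
    while (cur != .root_gate) {
      if (cur %in% seen) {
        validation_error("catalog: cycle in parent relation involving ", cur)
      }
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  rownames(df) <- NULL
  df
}

read_csv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA,
                  na.strings = character(0), check.names = TRUE)
}

coerce_numeric_cols <- function(df, cols) {
  for (cl in intersect(cols, names(df))) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  df
}

#' Read and validate an observation CSV
#'
#' @param path CSV file with header
#'   `individual_id,visit_index,collection_date,sex,age_years,subset_id,frequency_pct`.
#' @inheritParams validate_observations
#' @return validated observation data frame; empty `collection_date` becomes `NA`.
#' @export
read_observations <- function(path, catalog = NULL,
                              mode = c("strict", "lenient")) {
  df <- read_csv_table(path)
  df <- check_columns(df, .obs_cols, "observations")
  df$collection_date[df$collection_date == ""] <- NA_character_
  df <- coerce_numeric_cols(df, c("visit_index", "age_years", "frequency_pct"))
  validate_observations(df, catalog = catalog, mode = match.arg(mode))
}

#' Read and validate a replicate CSV
#' @inheritParams read_observations
#' @export
read_replicates <- function(path, catalog = NULL,
                            mode = c("strict", "lenient")) {
  df <- read_csv_table(path)
  df <- check_columns(df, .rep_cols, "replicates")
  df <- coerce_numeric_cols(df, "frequency_pct")
  validate_replicates(df, catalog = catalog, mode = match.arg(mode))
}

#' Read and validate a sibling-cohort CSV
#' @inheritParams read_observations
#' @export
read_siblings <- function(path, catalog = NULL,
                          mode = c("strict", "lenient")) {
  df <- read_csv_table(path)
  df <- check_columns(df, .sib_cols, "siblings")
  df <- coerce_numeric_cols(df, c("age_years", "frequency_pct"))
  validate_siblings(df, catalog = catalog, mode = match.arg(mode))
}

#' Read and validate a subset-catalog CSV
#' @param path CSV with header `subset_id,label,parent_gate_id,marker_text`.
#' @export
read_catalog <- function(path) {
  validate_catalog(read_csv_table(path))
}

#' Write any package table as UTF-8 CSV
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip reproduces every value bit for bit; `NA` in optional
#' character fields becomes the empty string.
#'
#' @param table data frame.
#' @param path output path.
#' @export
write_table <- function(table, path) {
  out <- table
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]])) {
      out[[cl]] <- sprintf("%.17g", out[[cl]])
    } else if (is.character(out[[cl]])) {
      out[[cl]][is.na(out[[cl]])] <- ""
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-individual visit counts and per-subset coverage
#'
#' Individuals with fewer than 2 visits cannot contribute a within-individual
#' variance and are flagged as ineligible; per subset, missing cells are the
#' (individual, visit) combinations present in the design but lacking a record
#' for that subset.
#'
#' @param obs validated observation table.
#' @return list with `individuals` (individual_id, n_visits, eligible_within),
#'   `subsets` (subset_id, n_observed, n_missing), and `complete` (logical).
#' @export
completeness_report <- function(obs) {
  visits_by_ind <- tapply(obs$visit_index, obs$individual_id,
                          function(v) length(unique(v)))
  individuals <- data.frame(
    individual_id = names(visits_by_ind),
    n_visits = as.integer(visits_by_ind),
    eligible_within = as.integer(visits_by_ind) >= 2L,
    stringsAsFactors = FALSE
  )
  design <- unique(obs[c("individual_id", "visit_index")])
  n_cells <- nrow(design)
  subsets <- lapply(split(obs, obs$subset_id), function(d) {
    have <- nrow(unique(d[c("individual_id", "visit_index")]))
    data.frame(subset_id = d$subset_id[1L], n_observed = have,
               n_missing = n_cells - have, stringsAsFactors = FALSE)
  })
  subsets <- do.call(rbind, subsets)
  rownames(subsets) <- NULL
  list(individuals = individuals, subsets = subsets,
       complete = all(individuals$eligible_within) && all(subsets$n_missing == 0L))
}

#' Default 35-entry subset catalog
#'
#' The catalog used by the synthetic study: the standard PBMC gating panel of
#' B, T, NK, monocyte and dendritic-cell subsets (33 field-standard labels)
#' plus two additional synthetic subsets to exercise catalog-driven exclusion;
#' all frequencies are percent of the listed parent gate.
#'
#' @return validated catalog data frame with 35 rows.
#' @export
default_subset_catalog <- function() {
  e <- function(id, label, parent, markers = "") {
    data.frame(subset_id = id, label = label, parent_gate_id = parent,
               marker_text = markers, stringsAsFactors = FALSE)
  }
  df <- rbind(
    e("t_cell", "T cell", .root_gate, "CD3+"),
    e("cd4", "CD4", "t_cell", "CD3+CD4+"),
    e("cd8", "CD8", "t_cell", "CD3+CD8+"),
    e("gd_t", "Gamma delta T cell", "t_cell", "CD3+gdTCR+"),
    e("nkt", "NKT", "t_cell", "CD3+CD56+"),
    e("inkt", "iNKT", "t_cell", "CD3+Va24Ja18+"),
    e("cd4_naive", "CD4 naive", "cd4", "CD45RA+CCR7+"),
    e("cd4_memory", "CD4 memory", "cd4", "CD45RO+"),
    e("cd4_emra", "CD4 EMRA", "cd4", "CD45RA+CCR7-"),
    e("treg", "Treg", "cd4", "CD25+CD127lo"),
    e("ntreg", "nTreg", "treg", "Helios+"),
    e("itreg", "iTreg", "treg", "Helios-"),
    e("cd39_treg", "CD39+ Treg", "treg", "CD39+"),
    e("cd39_ntreg", "CD39+ nTreg", "ntreg", "CD39+Helios+"),
    e("cd39_itreg", "CD39+ iTreg", "itreg", "CD39+Helios-"),
    e("cd8_naive", "CD8 naive", "cd8", "CD45RA+CCR7+"),
    e("cd8_memory", "CD8 memory", "cd8", "CD45RO+"),
    e("cd8_emra", "CD8 EMRA", "cd8", "CD45RA+CCR7-"),
    e("b_cell", "B cell", .root_gate, "CD19+"),
    e("b_naive", "B naive", "b_cell", "IgD+CD27-"),
    e("b_memory", "B memory", "b_cell", "CD27+"),
    e("b_immature", "B immature", "b_cell", "CD10+"),
    e("b1", "B1 B cell", "b_cell", "CD20+CD27+CD43+"),
    e("plasmablast", "Plasmablast", "b_cell", "CD27hiCD38hi"),
    e("plasmablast_iga", "Plasmablast IgA+", "plasmablast", "IgA+"),
    e("nk_cell", "NK cell", .root_gate, "CD3-CD56+"),
    e("monocyte", "Monocyte", .root_gate, "CD14+"),
    e("mono_classical", "Monocyte Classical", "monocyte", "CD14++CD16-"),
    e("mono_inflammatory", "Monocyte Inflammatory", "monocyte", "CD14++CD16+"),
    e("mono_patrolling", "Monocyte Patrolling", "monocyte", "CD14+CD16++"),
    e("dc", "Dendritic cell", .root_gate, "Lin-HLA-DR+"),
    e("mdc", "mDC", "dc", "CD11c+"),
    e("pdc", "pDC", "dc", "CD123+"),
    e("plasmablast_igg_syn", "Plasmablast IgG+ (synthetic)", "plasmablast", "IgG+"),
    e("nkt_cd8_syn", "NKT CD8+ (synthetic)", "nkt", "CD8+")
  )
  validate_catalog(df)
}
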