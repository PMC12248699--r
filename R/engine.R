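# The evidence-framework engine: eligibility gate, evidence-vector
# derivation, and classification through the declarative scenario table.

#' Eligibility gate
#'
#' The framework only assesses monoallelic (heterozygous) germline VHL
#' variants in patients evaluated at a genetics clinic with no
#' pathogenic/likely pathogenic germline finding in a
#' differential-diagnosis gene. Checked in order: presence of a germline
#' variant, zygosity, differential findings, genetics evaluation.
#'
#' @param case A one-row validated case table.
#' @return A list with `eligible` (logical) and `gate_reason` (one of
#'   `"no_germline_variant"`, `"non_heterozygous"`,
#'   `"differential_positive"`, `"not_evaluated"`, or `NA` when
#'   eligible).
#' @export
gate <- function(case) {
  stopifnot(nrow(case) == 1)
  has_variant <- !is.na(case$vhl_hgvs_c) ||
    length(case$deleted_exons[[1]]) > 0
  if (!has_variant) {
    return(list(eligible = FALSE, gate_reason = "no_germline_variant"))
  }
  if (!identical(case$zygosity, "heterozygous")) {
    return(list(eligible = FALSE, gate_reason = "non_heterozygous"))
  }
  dif <- case$differential_findings[[1]]
  if (any(dif$classification %in% c("P", "LP"))) {
    return(list(eligible = FALSE, gate_reason = "differential_positive"))
  }
  if (!isTRUE(case$evaluated_in_genetics)) {
    return(list(eligible = FALSE, gate_reason = "not_evaluated"))
  }
  list(eligible = TRUE, gate_reason = NA_character_)
}

#' Derive the discrete evidence vector of a case
#'
#' Reduces a validated case to the discrete quantities the scenario table
#' reasons over: the VHL component tumor count T (bilateral tumors count
#' per laterality; SDH-deficient paragangliomas are excluded), the RCC
#' count R within T, feature and non-VHL-tumor flags, the family-history
#' state (positive only for a first/second-degree relative diagnosed
#' with VHL syndrome), the somatic allelic status of the component-tumor
#' profile (after QC filtering), and the age band (young below the
#' configured threshold).
#'
#' @param case A one-row validated case table.
#' @param cfg A [vef_config()].
#' @return A one-row tibble with columns `subject_id`, `eligible`,
#'   `gate_reason`, `n_vhl_tumors`, `n_rcc`, `has_vhl_feature`,
#'   `has_non_vhl_tumor`, `family_history`, `somatic_available`,
#'   `somatic_status`, `age_band`, `germline_class`.
#' @export
derive_vector <- function(case, cfg = vef_config()) {
  stopifnot(nrow(case) == 1)
  g <- gate(case)
  tum <- case$personal_tumors[[1]]
  counted <- tum[tum$tumor_type %in% vhl_component_tumors() &
                   !(tum$tumor_type == "paraganglioma" &
                       tum$sdh_deficient), , drop = FALSE]
  n_t <- sum(counted$laterality_count)
  n_r <- sum(counted$laterality_count[counted$tumor_type == "rcc"])

  fam_raw <- case$family_history_vhl
  deg <- case$family_degree
  fam <- if (identical(fam_raw, "positive")) {
    if (!is.na(deg) && deg == "other") "negative" else "positive"
  } else if (identical(fam_raw, "negative")) "negative" else "unknown"

  somatic_available <- isTRUE(case$somatic_tested)
  if (somatic_available) {
    som <- qc_filter(case$somatic[[1]], cfg$qc)
    som <- som[som$qc_pass, , drop = FALSE]
    sdh_sources <- tum$tumor_type[tum$sdh_deficient]
    component <- is.na(som$tumor_source) |
      (som$tumor_source %in% vhl_component_tumors() &
         !som$tumor_source %in% sdh_sources)
    excluded_any <- any(!component)
    som <- som[component, , drop = FALSE]
    status <- if (nrow(som) == 0 && excluded_any) "uninformative"
              else allelic_status(som)$status
  } else {
    status <- "uninformative"
  }

  age_band <- if (is.na(case$age_years)) "unknown"
              else if (case$age_years < cfg$age_young_threshold) "young"
              else "adult"

  tibble::tibble(
    subject_id = case$subject_id,
    eligible = g$eligible,
    gate_reason = g$gate_reason,
    n_vhl_tumors = as.integer(n_t),
    n_rcc = as.integer(n_r),
    has_vhl_feature = length(case$personal_features[[1]]) > 0,
    has_non_vhl_tumor = length(case$non_vhl_tumors[[1]]) > 0,
    family_history = fam,
    somatic_available = somatic_available,
    somatic_status = status,
    age_band = age_band,
    germline_class = case$vhl_classification)
}

#' @rdname derive_vector
#' @param cases A validated case table (any number of rows).
#' @export
derive_vectors <- function(cases, cfg = vef_config()) {
  purrr::map_dfr(seq_len(nrow(cases)),
                 function(i) derive_vector(cases[i, ], cfg))
}

#' Canonical evidence-pattern string
#'
#' Serializes the discretized evidence-vector fields (never raw ages or
#' identifiers) into a canonical string; two vectors collide iff they are
#' field-wise equal. This is the de-identified unit the pattern
#' quantifier counts.
#'
#' @param vector A one-or-more-row evidence-vector tibble.
#' @return Character vector of pattern strings.
#' @export
evidence_pattern <- function(vector) {
  b <- function(x) ifelse(x, "1", "0")
  paste0("T=", vector$n_vhl_tumors,
         "|R=", vector$n_rcc,
         "|feature=", b(vector$has_vhl_feature),
         "|non_vhl_tumor=", b(vector$has_non_vhl_tumor),
         "|family=", vector$family_history,
         "|somatic=", b(vector$somatic_available),
         "|status=", vector$somatic_status,
         "|age=", vector$age_band,
         "|class=", ifelse(is.na(vector$germline_class), "NA",
                           vector$germline_class))
}

# ---- scenario table -------------------------------------------------

#' Load and validate a scenario table
#'
#' `load_scenario_table()` reads a YAML rule file (default: the table
#' shipped with the package) and validates it: exactly the 17 codes must
#' be present, each code's roman prefix must match its category
#' (I Positive, II Neutral, III Negative, IV NOS), and the rules must be
#' total and pairwise disjoint over the exhaustively enumerated
#' discretized evidence-vector space. Loading fails with
#' `"table_invalid"` otherwise.
#'
#' @param path YAML file path; `NULL` loads the packaged default.
#' @return A list of class `scenario_table` with `metadata` and `rules`
#'   (a tibble with `id`, `code`, `category`, `priority`, `when`
#'   list-column, `comment`).
#' @export
load_scenario_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "vef_vhl_scenarios.yaml",
                                package = "vhlvef", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  rules <- purrr::map_dfr(raw$rules, function(r) {
    tibble::tibble(id = r$id, code = r$code, category = r$category,
                   priority = as.integer(r$priority), when = list(r$when),
                   comment = stringr::str_squish(r$comment))
  })
  table <- structure(list(metadata = raw$metadata, rules = rules),
                     class = "scenario_table")
  validate_scenario_table(table)
  table
}

#' @rdname load_scenario_table
#' @param table A `scenario_table`.
#' @export
validate_scenario_table <- function(table) {
  rules <- table$rules
  missing_codes <- setdiff(vef_codes(), rules$code)
  extra_codes <- setdiff(rules$code, vef_codes())
  if (length(missing_codes) > 0 || length(extra_codes) > 0) {
    stop("table_invalid: code set mismatch (missing: ",
         paste(missing_codes, collapse = ", "), "; unknown: ",
         paste(extra_codes, collapse = ", "), ")")
  }
  bad_cat <- rules$category != code_category(rules$code)
  if (any(bad_cat)) {
    stop("table_invalid: category does not match code prefix for rule(s) ",
         paste(rules$id[bad_cat], collapse = ", "))
  }
  space <- enumerate_vector_space()
  hits <- matrix(FALSE, nrow(space), nrow(rules))
  for (j in seq_len(nrow(rules))) {
    hits[, j] <- rule_matches(rules$when[[j]], space)
  }
  n_match <- rowSums(hits)
  if (any(n_match == 0)) {
    ex <- space[which(n_match == 0)[1], ]
    stop("table_invalid: not total; unmatched vector e.g. ",
         paste(names(ex), unlist(ex), sep = "=", collapse = " "))
  }
  if (any(n_match > 1)) {
    i <- which(n_match > 1)[1]
    stop("table_invalid: rules not disjoint (",
         paste(rules$id[hits[i, ]], collapse = ", "), " overlap)")
  }
  invisible(table)
}

# Exhaustive grid of syntactically valid discretized evidence vectors.
# Tumor counts are truncated at 3 (every rule condition saturates at 2),
# R <= T, and somatic_status is uninformative whenever somatic data are
# unavailable.
enumerate_vector_space <- function() {
  tr <- dplyr::bind_rows(purrr::map(0:3, function(t) {
    tibble::tibble(n_vhl_tumors = t, n_rcc = 0:min(t, 3))
  }))
  ss <- dplyr::bind_rows(
    tibble::tibble(somatic_available = FALSE,
                   somatic_status = "uninformative"),
    tibble::tibble(somatic_available = TRUE,
                   somatic_status = somatic_statuses()))
  eligible <- tidyr::expand_grid(
    eligible = TRUE, gate_reason = NA_character_, tr,
    has_vhl_feature = c(FALSE, TRUE),
    has_non_vhl_tumor = c(FALSE, TRUE),
    family_history = c("positive", "negative", "unknown"),
    ss,
    age_band = c("young", "adult", "unknown"),
    germline_class = NA_character_)
  ineligible <- tidyr::expand_grid(
    eligible = FALSE,
    gate_reason = c("no_germline_variant", "non_heterozygous",
                    "differential_positive", "not_evaluated"),
    tr[1, ], has_vhl_feature = FALSE, has_non_vhl_tumor = FALSE,
    family_history = "unknown", ss[1, ], age_band = "unknown",
    germline_class = NA_character_)
  dplyr::bind_rows(eligible, ineligible)
}

# Evaluate one rule's conjunction over the rows of an evidence-vector
# tibble; returns a logical vector.
rule_matches <- function(when, vectors) {
  ok <- rep(TRUE, nrow(vectors))
  for (field in names(when)) {
    cond <- when[[field]]
    val <- vectors[[field]]
    if (is.null(val)) stop("table_invalid: unknown field '", field, "'")
    ok <- ok & if (is.list(cond) && !is.null(names(cond))) {
      pass <- rep(TRUE, length(val))
      if (!is.null(cond$min)) pass <- pass & val >= cond$min
      if (!is.null(cond$max)) pass <- pass & val <= cond$max
      pass
    } else if (length(cond) > 1 || is.list(cond)) {
      val %in% unlist(cond)
    } else {
      !is.na(val) & val == cond
    }
  }
  ok
}

#' Classify an evidence vector
#'
#' Matches the vector against the scenario table (rules in ascending
#' priority; the validated table makes priority irrelevant because the
#' rules are disjoint) and returns the scenario code, its category, the
#' explanatory comment, the matched rule id, and the canonical evidence
#' pattern. A vector matching no rule falls back to the table's fallback
#' code (default IV-I).
#'
#' @param vector A one-or-more-row evidence-vector tibble (from
#'   [derive_vectors()]).
#' @param table A validated [load_scenario_table()] result.
#' @return A tibble with columns `subject_id` (when present), `vef_code`,
#'   `vef_category`, `comment`, `matched_rule_id`, `evidence_pattern`.
#' @export
classify_vector <- function(vector, table = load_scenario_table()) {
  rules <- dplyr::arrange(table$rules, .data$priority)
  hits <- matrix(FALSE, nrow(vector), nrow(rules))
  for (j in seq_len(nrow(rules))) {
    hits[, j] <- rule_matches(rules$when[[j]], vector)
  }
  first <- apply(hits, 1, function(h) {
    w <- which(h)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  fallback <- table$metadata$fallback_code %||% "IV-I"
  out <- tibble::tibble(
    vef_code = ifelse(is.na(first), fallback, rules$code[first]),
    vef_category = ifelse(is.na(first), code_category(fallback),
                          rules$category[first]),
    comment = ifelse(is.na(first), "No scenario rule matched.",
                     rules$comment[first]),
    matched_rule_id = ifelse(is.na(first), NA_character_,
                             rules$id[first]),
    evidence_pattern = evidence_pattern(vector))
  if ("subject_id" %in% names(vector)) {
    out <- dplyr::bind_cols(tibble::tibble(
      subject_id = vector$subject_id), out)
  }
  out
}
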