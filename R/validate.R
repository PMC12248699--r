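#' Validate a case table
#'
#' Checks every case against the evidence-model invariants and normalizes
#' controlled-vocabulary terms (case-insensitive, whitespace-tolerant;
#' "favor polymorphism" is normalized to LB). The result is the normalized
#' table with two added columns: `.valid` (logical) and `.issues`
#' (list-column of character vectors, each `"code: message"`). Validation
#' is idempotent: validating an already-valid table returns an identical
#' table.
#'
#' @param cases A case table (from [case_record()], [read_case_table()] or
#'   [read_cases_json()]).
#' @param strict When `TRUE`, any violation raises an error instead of
#'   being recorded.
#' @return The normalized case table with `.valid` and `.issues` columns.
#' @seealso [case_issues()] for the issues in long format.
#' @export
validate_cases <- function(cases, strict = FALSE) {
  cases <- dplyr::select(cases, -dplyr::any_of(c(".valid", ".issues")))
  stopifnot(all(case_table_columns() %in% names(cases)))
  if (nrow(cases) == 0) {
    return(dplyr::mutate(cases, .valid = logical(0), .issues = list()))
  }

  dup_ids <- cases$subject_id[duplicated(cases$subject_id)]
  out <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    row <- normalize_case(cases[i, ])
    issues <- check_case(row)
    if (row$subject_id %in% dup_ids) {
      issues <- c(issues, paste0("duplicate_subject: subject_id '",
                                 row$subject_id, "' occurs more than once"))
    }
    row$.valid <- length(issues) == 0
    row$.issues <- list(issues)
    row
  })
  if (strict && !all(out$.valid)) {
    stop("invalid case records: ",
         paste(unlist(out$.issues), collapse = "; "))
  }
  out
}

#' Validation issues in long format
#'
#' @param validated A table from [validate_cases()].
#' @return A tibble with columns `subject_id`, `code`, `message`.
#' @export
case_issues <- function(validated) {
  stopifnot(".issues" %in% names(validated))
  tidyr::unnest(
    tibble::tibble(subject_id = validated$subject_id,
                   issue = validated$.issues),
    "issue") |>
    dplyr::mutate(
      code = stringr::str_extract(.data$issue, "^[a-z_]+"),
      message = stringr::str_remove(.data$issue, "^[a-z_]+: ")) |>
    dplyr::select("subject_id", "code", "message")
}

# term normalization applied before checking
normalize_case <- function(row) {
  cls <- row$vhl_classification
  if (!is.na(cls)) {
    cls <- toupper(normalize_term(cls))
    if (cls %in% c("FAVOR_POLYMORPHISM", "FP")) cls <- "LB"
    row$vhl_classification <- cls
  }
  row$zygosity <- normalize_term(row$zygosity)
  row$sex <- normalize_term(row$sex)
  row$family_history_vhl <- normalize_term(row$family_history_vhl)
  if (!is.na(row$family_degree)) {
    row$family_degree <- normalize_term(row$family_degree)
  }
  row$personal_features <- list(normalize_term(row$personal_features[[1]]))
  tum <- row$personal_tumors[[1]]
  if (nrow(tum) > 0) tum$tumor_type <- normalize_term(tum$tumor_type)
  row$personal_tumors <- list(tum)
  dif <- row$differential_findings[[1]]
  if (nrow(dif) > 0) {
    dif$gene <- toupper(stringr::str_trim(dif$gene))
    dif$classification <- toupper(normalize_term(dif$classification))
    dif$classification[dif$classification %in%
                         c("FAVOR_POLYMORPHISM", "FP")] <- "LB"
  }
  row$differential_findings <- list(dif)
  som <- row$somatic[[1]]
  if (nrow(som) > 0) {
    som$alteration_type <- normalize_term(som$alteration_type)
    src <- som$tumor_source
    som$tumor_source[!is.na(src)] <- normalize_term(src[!is.na(src)])
  }
  row$somatic <- list(som)
  row$deleted_exons <- list(sort(unique(row$deleted_exons[[1]])))
  row
}

check_case <- function(row) {
  issues <- character(0)
  add <- function(code, msg) c(issues, paste0(code, ": ", msg))

  if (is.na(row$subject_id) || !nzchar(row$subject_id)) {
    issues <- add("missing_field", "subject_id is empty")
  }
  has_cn <- length(row$deleted_exons[[1]]) > 0
  if (!is.na(row$vhl_hgvs_c) && !has_cn &&
      !is_parseable_cdna(row$vhl_hgvs_c)) {
    issues <- add("bad_hgvs",
                  paste0("vhl_hgvs_c '", row$vhl_hgvs_c,
                         "' is not a recognized cDNA description"))
  }
  if (has_cn && !all(row$deleted_exons[[1]] %in% 1:3)) {
    issues <- add("unknown_term", "deleted_exons must be a subset of 1-3")
  }
  if (!is.na(row$vhl_classification) &&
      !row$vhl_classification %in% germline_classifications()) {
    issues <- add("unknown_term",
                  paste0("vhl_classification '", row$vhl_classification,
                         "' not in {",
                         paste(germline_classifications(), collapse = ", "),
                         "}"))
  }
  if (!row$zygosity %in% zygosity_levels()) {
    issues <- add("unknown_term",
                  paste0("zygosity '", row$zygosity, "'"))
  }
  if (!row$sex %in% c("female", "male", "unknown")) {
    issues <- add("unknown_term", paste0("sex '", row$sex, "'"))
  }
  if (!is.na(row$age_years) && row$age_years < 0) {
    issues <- add("bad_value", "age_years must be non-negative")
  }

  dif <- row$differential_findings[[1]]
  bad_genes <- setdiff(dif$gene, vhl_differential_genes())
  if (length(bad_genes) > 0) {
    issues <- add("unknown_term",
                  paste0("differential gene(s) not on the 13-gene panel: ",
                         paste(bad_genes, collapse = ", ")))
  }
  bad_cls <- setdiff(dif$classification, c("P", "LP", "VUS", "LB", "B"))
  if (length(bad_cls) > 0) {
    issues <- add("unknown_term",
                  paste0("differential classification(s): ",
                         paste(bad_cls, collapse = ", ")))
  }

  tum <- row$personal_tumors[[1]]
  bad_types <- setdiff(tum$tumor_type, vhl_component_tumors())
  if (length(bad_types) > 0) {
    issues <- add("unknown_term",
                  paste0("personal_tumors type(s) outside the component-",
                         "tumor vocabulary: ",
                         paste(bad_types, collapse = ", "),
                         " (non-VHL tumors belong in non_vhl_tumors)"))
  }
  if (any(is.na(tum$laterality_count) | tum$laterality_count < 1)) {
    issues <- add("bad_value", "laterality_count must be >= 1")
  }
  if (any(tum$sdh_deficient & tum$tumor_type != "paraganglioma")) {
    issues <- add("bad_value",
                  "sdh_deficient may be TRUE only for paraganglioma")
  }
  bad_feat <- setdiff(row$personal_features[[1]], vhl_features())
  if (length(bad_feat) > 0) {
    issues <- add("unknown_term",
                  paste0("personal_features: ",
                         paste(bad_feat, collapse = ", ")))
  }

  if (!row$family_history_vhl %in% c("positive", "negative", "unknown")) {
    issues <- add("unknown_term",
                  paste0("family_history_vhl '", row$family_history_vhl,
                         "'"))
  }
  if (!is.na(row$family_degree)) {
    if (!identical(row$family_history_vhl, "positive")) {
      issues <- add("bad_value",
                    "family_degree present only when family_history_vhl is positive")
    }
    if (!row$family_degree %in% c("first", "second", "other")) {
      issues <- add("unknown_term",
                    paste0("family_degree '", row$family_degree, "'"))
    }
  }

  som <- row$somatic[[1]]
  if (!row$somatic_tested && nrow(som) > 0) {
    issues <- add("bad_value",
                  "somatic alterations present but somatic_tested is FALSE")
  }
  if (nrow(som) > 0) {
    bad_t <- setdiff(som$alteration_type, somatic_alteration_types())
    if (length(bad_t) > 0) {
      issues <- add("unknown_term",
                    paste0("somatic alteration_type(s): ",
                           paste(bad_t, collapse = ", ")))
    }
    seq_like <- som$alteration_type %in% c("snv", "indel")
    if (any(seq_like & is.na(som$hgvs_c))) {
      issues <- add("missing_field", "snv/indel records must carry hgvs_c")
    }
    if (any(!seq_like & !is.na(som$vaf_percent))) {
      issues <- add("bad_value", "vaf_percent applies to snv/indel only")
    }
    if (any(!is.na(som$vaf_percent) &
            (som$vaf_percent < 0 | som$vaf_percent > 100))) {
      issues <- add("bad_value", "vaf_percent must lie in [0, 100]")
    }
  }
  issues
}
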