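#' Encode a case table through the evidence framework
#'
#' The batch pipeline: validate every case, derive its evidence vector,
#' classify it through the scenario table, and return the input table
#' with the scenario code, category, comment, evidence pattern and gate
#' reason appended (one output row per input row, subject ids
#' preserved). Rows that fail validation are carried through with the
#' fallback code IV-I and the validation message in `comment`; with
#' `strict = TRUE` they abort instead.
#'
#' @param cases A case table (from [read_case_table()],
#'   [read_cases_json()] or [case_record()] rows).
#' @param table A validated scenario table.
#' @param cfg A [vef_config()].
#' @param strict Abort on invalid rows (and duplicate subject ids)
#'   instead of carrying them through.
#' @return An object of class `vef_encoding`: a list with `table` (the
#'   encoded tibble), `report` (per-code and per-category counts), and
#'   `metadata`. Use [tidy()][generics::tidy] for the encoded tibble and
#'   [glance()][generics::glance] for the run summary.
#' @examples
#' cases <- vef_fixture("patients_21_23")
#' enc <- encode_cases(cases)
#' dplyr::select(tidy(enc), subject_id, vef_code, vef_category)
#' @export
encode_cases <- function(cases, table = load_scenario_table(),
                         cfg = vef_config(), strict = FALSE) {
  validated <- validate_cases(cases, strict = strict)
  if (nrow(validated) == 0) {
    encoded <- dplyr::mutate(
      validated, vef_code = character(0), vef_category = character(0),
      comment = character(0), matched_rule_id = character(0),
      evidence_pattern = character(0), gate_reason = character(0))
    return(new_vef_encoding(encoded, table, cfg))
  }
  fallback <- table$metadata$fallback_code %||% "IV-I"

  classified <- purrr::map_dfr(seq_len(nrow(validated)), function(i) {
    row <- validated[i, ]
    if (!row$.valid) {
      return(tibble::tibble(
        vef_code = fallback, vef_category = code_category(fallback),
        comment = paste0("Validation failed: ",
                         paste(row$.issues[[1]], collapse = "; ")),
        matched_rule_id = NA_character_,
        evidence_pattern = NA_character_,
        gate_reason = "invalid_record"))
    }
    vec <- derive_vector(row, cfg)
    cls <- classify_vector(vec, table)
    tibble::tibble(
      vef_code = cls$vef_code, vef_category = cls$vef_category,
      comment = cls$comment, matched_rule_id = cls$matched_rule_id,
      evidence_pattern = cls$evidence_pattern,
      gate_reason = vec$gate_reason)
  })
  encoded <- dplyr::bind_cols(
    dplyr::select(validated, -dplyr::any_of(
      c("vef_code", "vef_category", "comment", "matched_rule_id",
        "evidence_pattern", "gate_reason"))),
    classified)
  new_vef_encoding(encoded, table, cfg)
}

new_vef_encoding <- function(encoded, table, cfg) {
  by_code <- dplyr::count(encoded, .data$vef_code, name = "n")
  by_category <- dplyr::count(encoded, .data$vef_category, name = "n")
  structure(
    list(table = encoded,
         report = list(n_cases = nrow(encoded),
                       n_invalid = sum(!encoded$.valid),
                       by_code = by_code, by_category = by_category),
         metadata = list(scenario_version = table$metadata$version,
                         age_young_threshold = cfg$age_young_threshold)),
    class = "vef_encoding")
}

#' @export
print.vef_encoding <- function(x, ...) {
  cat("<vef_encoding> ", x$report$n_cases, " case(s), ",
      x$report$n_invalid, " invalid\n", sep = "")
  print(x$report$by_category)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an encoding
#'
#' `tidy()` returns the encoded table (one row per case with the
#' appended classification columns); `glance()` a one-row run summary
#' with the case count, invalid count, and per-category counts.
#'
#' @param x A `vef_encoding`.
#' @param ... Unused.
#' @export
tidy.vef_encoding <- function(x, ...) x$table

#' @rdname tidy.vef_encoding
#' @export
glance.vef_encoding <- function(x, ...) {
  base <- tibble::tibble(n_cases = x$report$n_cases,
                         n_invalid = x$report$n_invalid)
  by_cat <- x$report$by_category
  if (nrow(by_cat) == 0) return(base)
  cat_counts <- stats::setNames(as.list(by_cat$n),
                                paste0("n_", tolower(by_cat$vef_category)))
  dplyr::bind_cols(base, tibble::as_tibble(cat_counts))
}

#' Assign fresh opaque subject identifiers
#'
#' Replaces (or creates) `subject_id` with seeded, reproducible opaque
#' identifiers carrying no subject information.
#'
#' @param cases A case table.
#' @param seed Integer seed; the same input and seed give identical ids.
#' @param prefix Identifier prefix.
#' @return The table with fresh `subject_id`.
#' @export
assign_subject_ids <- function(cases, seed = 1L, prefix = "SUBJ") {
  n <- nrow(cases)
  ids <- withr::with_seed(seed, {
    paste0(prefix, "-",
           formatC(sample.int(.Machine$integer.max, n), width = 10,
                   flag = "0"))
  })
  cases$subject_id <- ids
  cases
}

#' Plot the code distribution of an encoding
#'
#' Bar chart of case counts by scenario code, filled by category.
#'
#' @param object A `vef_encoding`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vef_encoding <- function(object, ...) {
  df <- dplyr::count(object$table, .data$vef_code, .data$vef_category)
  df$vef_code <- factor(df$vef_code, levels = vef_codes())
  df$vef_category <- factor(df$vef_category, levels = vef_categories())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vef_code, y = .data$n,
                                   fill = .data$vef_category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      Positive = "#1b7837", Neutral = "#762a83", Negative = "#c2a5cf",
      NOS = "grey60"), drop = FALSE) +
    ggplot2::labs(x = "scenario code", y = "cases", fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
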