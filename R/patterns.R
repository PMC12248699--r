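# Per-variant recurrence and unique evidence patterns across an encoded
# cohort.

#' Normalize a variant key
#'
#' Canonical key for counting a variant across subjects and institutions:
#' whitespace removed, the `VHL:` gene prefix dropped, case folded to the
#' conventional form (positions unchanged, nucleotides upper-case,
#' `c.`/`del`/`dup`/`ins` lower-case). Germline copy-number deletions are
#' keyed by their deleted-exon set (`del_exons_1-3`).
#'
#' @param hgvs_c cDNA string (vectorized).
#' @param deleted_exons Optional list of deleted-exon integer vectors;
#'   non-empty entries override `hgvs_c`.
#' @return Character vector of canonical keys.
#' @examples
#' normalize_variant_key("VHL: c.340+578c>t")  # "c.340+578C>T"
#' @export
normalize_variant_key <- function(hgvs_c, deleted_exons = NULL) {
  key <- purrr::map_chr(hgvs_c, function(h) {
    if (is.na(h)) return(NA_character_)
    x <- strip_gene_prefix(h)
    x <- stringr::str_replace_all(x, stringr::regex("^C\\.",
                                                    ignore_case = TRUE),
                                  "c.")
    # upper-case nucleotides, keep del/dup/ins/delins lower-case
    x <- toupper(x)
    x <- stringr::str_replace(x, "^C\\.", "c.")
    x <- stringr::str_replace_all(x, "DELINS", "delins")
    x <- stringr::str_replace_all(x, "DEL", "del")
    x <- stringr::str_replace_all(x, "DUP", "dup")
    x <- stringr::str_replace_all(x, "INS", "ins")
    x
  })
  if (!is.null(deleted_exons)) {
    cn <- lengths(deleted_exons) > 0
    key[cn] <- paste0("del_exons_", purrr::map_chr(
      deleted_exons[cn], ~ paste(sort(unique(.x)), collapse = "-")))
  }
  key
}

encoded_with_keys <- function(encoded) {
  if (inherits(encoded, "vef_encoding")) encoded <- encoded$table
  encoded$variant_key <- normalize_variant_key(encoded$vhl_hgvs_c,
                                               encoded$deleted_exons)
  encoded
}

#' Variant recurrence
#'
#' Counts the distinct subjects carrying a variant in an encoded cohort
#' (a subject contributes once even with duplicate rows). An unknown key
#' counts 0.
#'
#' @param encoded A `vef_encoding` or its [tidy()] table.
#' @param variant_key Variant to count (normalized before matching).
#' @return Integer count.
#' @export
variant_recurrence <- function(encoded, variant_key) {
  df <- encoded_with_keys(encoded)
  key <- normalize_variant_key(variant_key)
  length(unique(df$subject_id[!is.na(df$variant_key) &
                                df$variant_key == key]))
}

#' Unique evidence patterns of a variant
#'
#' Groups the subjects carrying a variant by their canonical evidence
#' pattern and counts each distinct pattern; patterns are returned in
#' deterministic order (descending count, then lexicographic pattern).
#' Pattern counts always sum to the variant's recurrence.
#'
#' @inheritParams variant_recurrence
#' @return A list with `variant_key`, `recurrence`, and `patterns` (a
#'   tibble with `pattern`, `vef_code`, `vef_category`, `count`).
#' @export
unique_patterns <- function(encoded, variant_key) {
  df <- encoded_with_keys(encoded)
  key <- normalize_variant_key(variant_key)
  df <- df[!is.na(df$variant_key) & df$variant_key == key, , drop = FALSE]
  df <- df[!duplicated(df$subject_id), , drop = FALSE]
  if (nrow(df) == 0) {
    return(list(variant_key = key, recurrence = 0L,
                patterns = tibble::tibble(
                  pattern = character(0), vef_code = character(0),
                  vef_category = character(0), count = integer(0))))
  }
  patterns <- df |>
    dplyr::count(.data$evidence_pattern, .data$vef_code,
                 .data$vef_category, name = "count") |>
    dplyr::rename(pattern = "evidence_pattern") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pattern)
  list(variant_key = key, recurrence = nrow(df), patterns = patterns)
}

#' Pattern summaries for every variant in a cohort
#'
#' @inheritParams variant_recurrence
#' @return A tibble with one row per distinct variant key: `variant_key`,
#'   `recurrence`, `n_patterns`, and a `patterns` list-column (as in
#'   [unique_patterns()]), ordered by descending recurrence then key.
#' @export
quantify_patterns <- function(encoded) {
  df <- encoded_with_keys(encoded)
  keys <- sort(unique(df$variant_key[!is.na(df$variant_key)]))
  if (length(keys) == 0) {
    return(tibble::tibble(variant_key = character(0),
                          recurrence = integer(0),
                          n_patterns = integer(0), patterns = list()))
  }
  out <- purrr::map_dfr(keys, function(k) {
    s <- unique_patterns(df, k)
    tibble::tibble(variant_key = s$variant_key,
                   recurrence = s$recurrence,
                   n_patterns = nrow(s$patterns),
                   patterns = list(s$patterns))
  })
  dplyr::arrange(out, dplyr::desc(.data$recurrence), .data$variant_key)
}
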