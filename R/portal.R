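# De-identified, shareable per-variant records: the data layer of a
# public variant portal. Records carry the variant key, gene region,
# recurrence, and the distinct de-identified evidence patterns with
# counts -- never subject ids, exact ages, or free-text clinical notes.

#' Build portal records from an encoded cohort
#'
#' Aggregates an encoded cohort into one de-identified record per
#' distinct variant: normalized key, gene region (from the transcript
#' map), recurrence, unique evidence patterns with counts, and the
#' scenario-table provenance. Records are ordered by variant key.
#'
#' @param encoded A `vef_encoding` or its [tidy()] table.
#' @param summaries Optional precomputed [quantify_patterns()] output for
#'   the same cohort; recomputed when `NULL`. Every summarized variant
#'   must be present in the encoded table (`"inconsistent_inputs"`
#'   otherwise).
#' @param tmap A transcript map.
#' @param table_version Scenario-table version string recorded on each
#'   record.
#' @return A tibble with one row per variant: `variant_key`, `region`,
#'   `recurrence`, `n_patterns`, `patterns` (list-column),
#'   `table_version`.
#' @export
build_portal <- function(encoded, summaries = NULL,
                         tmap = default_transcript_map(),
                         table_version = "1.0") {
  df <- encoded_with_keys(encoded)
  if (is.null(summaries)) summaries <- quantify_patterns(df)
  extra <- setdiff(summaries$variant_key,
                   df$variant_key[!is.na(df$variant_key)])
  if (length(extra) > 0) {
    stop("inconsistent_inputs: variant(s) in summaries but not in the ",
         "encoded table: ", paste(extra, collapse = ", "))
  }
  if (nrow(summaries) == 0) {
    out <- tibble::tibble(variant_key = character(0),
                          region = character(0), recurrence = integer(0),
                          n_patterns = integer(0), patterns = list(),
                          table_version = character(0))
    class(out) <- c("portal_records", class(out))
    return(out)
  }
  region_of <- function(key) {
    if (stringr::str_starts(key, "del_exons_")) {
      exons <- as.integer(stringr::str_split_1(
        stringr::str_remove(key, "del_exons_"), "-"))
      deletion_region(exons, tmap)
    } else if (is_parseable_cdna(key)) {
      map_region(parse_cdna(key), tmap)
    } else {
      NA_character_
    }
  }
  out <- summaries |>
    dplyr::mutate(region = purrr::map_chr(.data$variant_key, region_of),
                  table_version = table_version) |>
    dplyr::select("variant_key", "region", "recurrence", "n_patterns",
                  "patterns", "table_version") |>
    dplyr::arrange(.data$variant_key)
  class(out) <- c("portal_records", class(out))
  out
}

#' Query portal records for a variant
#'
#' Looks a variant up by normalized key (same normalization as
#' [normalize_variant_key()]); an unknown key returns an explicit empty
#' result, not an error.
#'
#' @param records [build_portal()] output.
#' @param variant_key Key to look up (any accepted spelling).
#' @return The matching one-row record, or a zero-row tibble.
#' @export
portal_query <- function(records, variant_key) {
  key <- normalize_variant_key(variant_key)
  records[!is.na(records$variant_key) & records$variant_key == key, ,
          drop = FALSE]
}

#' Write and read portal records
#'
#' `write_portal_json()` serializes records to canonical JSON (sorted by
#' variant key; nested pattern tables as arrays of objects);
#' `read_portal_json()` is its inverse. `write_portal_tsv()` writes a
#' flat one-row-per-pattern TSV view for spreadsheet users.
#'
#' @param records [build_portal()] output.
#' @param path Output path.
#' @return `path` invisibly (writers); a records tibble (reader).
#' @export
write_portal_json <- function(records, path) {
  objs <- purrr::map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    list(variant_key = r$variant_key, region = r$region,
         recurrence = r$recurrence, n_patterns = r$n_patterns,
         table_version = r$table_version,
         patterns = r$patterns[[1]])
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, dataframe = "rows",
                       na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_portal_json
#' @export
read_portal_json <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- purrr::map_dfr(objs, function(o) {
    patterns <- purrr::map_dfr(o$patterns, function(p) {
      tibble::tibble(pattern = p$pattern, vef_code = p$vef_code,
                     vef_category = p$vef_category,
                     count = as.integer(p$count))
    })
    tibble::tibble(variant_key = o$variant_key,
                   region = o$region %||% NA_character_,
                   recurrence = as.integer(o$recurrence),
                   n_patterns = as.integer(o$n_patterns),
                   patterns = list(patterns),
                   table_version = o$table_version)
  })
  class(out) <- c("portal_records", class(out))
  out
}

#' @rdname write_portal_json
#' @export
write_portal_tsv <- function(records, path) {
  flat <- records |>
    dplyr::select("variant_key", "region", "recurrence",
                  "table_version", "patterns") |>
    tidyr::unnest("patterns")
  readr::write_tsv(flat, path, na = "")
  invisible(path)
}

#' Plot the recurrence profile of portal records
#'
#' @param records [build_portal()] output.
#' @param top Show at most this many variants (by recurrence).
#' @return A ggplot object.
#' @export
plot_portal_recurrence <- function(records, top = 20) {
  df <- dplyr::slice_max(records, .data$recurrence, n = top,
                         with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variant_key, .data$recurrence),
    y = .data$recurrence)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "recurrence (distinct subjects)") +
    ggplot2::theme_minimal()
}
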