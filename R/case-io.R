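# Flat-text serialization of case tables.
#
# TSV schema (one row per case): subject_id, vhl_hgvs_c, vhl_classification,
# zygosity, deleted_exons ("1,2,3"), differential_findings ("GENE:CLASS;..."
# or "none"), evaluated_in_genetics, age_years, sex, personal_tumors
# ("type[:count][:sdh_deficient];..."), personal_features (";"-list),
# non_vhl_tumors (";"-list), family_history_vhl, family_degree,
# somatic_tested, somatic_alterations
# ("hgvs|type|vaf|log2|coverage|reads|pop_af|cosmic|source;...", empty
# fields allowed). Empty string encodes a missing value.

fmt_or_empty <- function(x) ifelse(is.na(x), "", as.character(x))
na_if_empty <- function(x) dplyr::na_if(stringr::str_trim(x), "")
split_list <- function(x, sep = ";") {
  if (is.na(x) || !nzchar(stringr::str_trim(x)) ||
      normalize_term(x) == "none") return(character(0))
  stringr::str_trim(stringr::str_split_1(x, stringr::fixed(sep)))
}

serialize_tumors <- function(tumors) {
  if (nrow(tumors) == 0) return("")
  paste(purrr::pmap_chr(tumors, function(tumor_type, laterality_count,
                                         sdh_deficient, ...) {
    s <- paste0(tumor_type, ":", laterality_count)
    if (isTRUE(sdh_deficient)) s <- paste0(s, ":sdh_deficient")
    s
  }), collapse = ";")
}

parse_tumors <- function(x) {
  items <- split_list(x)
  if (length(items) == 0) return(empty_tumors())
  purrr::map_dfr(items, function(it) {
    parts <- stringr::str_split_1(it, stringr::fixed(":"))
    n <- if (length(parts) >= 2 && nzchar(parts[2]))
      suppressWarnings(as.integer(parts[2])) else 1L
    sdh <- length(parts) >= 3 &&
      normalize_term(parts[3]) %in% c("sdh_deficient", "true", "1", "sdh")
    tumor_record(normalize_term(parts[1]), n, sdh)
  })
}

serialize_differentials <- function(df) {
  if (nrow(df) == 0) return("none")
  paste(paste0(df$gene, ":", df$classification), collapse = ";")
}

parse_differentials <- function(x) {
  items <- split_list(x)
  if (length(items) == 0) return(empty_differentials())
  purrr::map_dfr(items, function(it) {
    parts <- stringr::str_split_1(it, stringr::fixed(":"))
    tibble::tibble(gene = toupper(stringr::str_trim(parts[1])),
                   classification = toupper(stringr::str_trim(
                     parts[2] %||% NA_character_)))
  })
}

serialize_somatic <- function(df) {
  if (nrow(df) == 0) return("")
  paste(purrr::pmap_chr(df, function(hgvs_c, alteration_type, vaf_percent,
                                     log2_ratio, coverage, unique_reads,
                                     population_af_percent, cosmic_count,
                                     tumor_source) {
    paste(fmt_or_empty(c(hgvs_c, alteration_type, vaf_percent, log2_ratio,
                         coverage, unique_reads, population_af_percent,
                         cosmic_count, tumor_source)), collapse = "|")
  }), collapse = ";")
}

parse_somatic <- function(x) {
  items <- split_list(x)
  if (length(items) == 0) return(empty_somatic())
  purrr::map_dfr(items, function(it) {
    f <- stringr::str_trim(stringr::str_split_1(it, stringr::fixed("|")))
    f <- c(f, rep("", max(0, 9 - length(f))))
    num <- function(i) if (nzchar(f[i]))
      suppressWarnings(as.numeric(f[i])) else NA_real_
    somatic_alteration(
      hgvs_c = na_if_empty(f[1]),
      alteration_type = normalize_term(f[2]),
      vaf_percent = num(3), log2_ratio = num(4),
      coverage = num(5), unique_reads = num(6),
      population_af_percent = num(7), cosmic_count = num(8),
      tumor_source = if (nzchar(f[9])) normalize_term(f[9])
                     else NA_character_)
  })
}

parse_bool <- function(x) {
  normalize_term(fmt_or_empty(x)) %in% c("true", "t", "1", "yes")
}

#' Read and write case tables
#'
#' `read_case_table()` reads the UTF-8 TSV case schema into a case table
#' (one row per case, list-columns for repeated axes); `write_case_table()`
#' is its inverse. `read_cases_json()` / `write_cases_json()` do the same
#' through an equivalent JSON representation (an array of case objects).
#' Reading does not validate; pass the result to [validate_cases()].
#'
#' @param path File path.
#' @param cases A case table (as from [case_record()] /
#'   [read_case_table()]).
#' @return A case table tibble (readers) or `path`, invisibly (writers).
#' @export
read_case_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  required <- c("subject_id", "vhl_hgvs_c", "vhl_classification", "zygosity",
                "deleted_exons", "differential_findings",
                "evaluated_in_genetics", "age_years", "sex",
                "personal_tumors", "personal_features", "non_vhl_tumors",
                "family_history_vhl", "family_degree", "somatic_tested",
                "somatic_alterations")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("case table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) return(case_record(character(0))[0, ])
  purrr::pmap_dfr(raw, function(subject_id, vhl_hgvs_c, vhl_classification,
                                zygosity, deleted_exons,
                                differential_findings, evaluated_in_genetics,
                                age_years, sex, personal_tumors,
                                personal_features, non_vhl_tumors,
                                family_history_vhl, family_degree,
                                somatic_tested, somatic_alterations, ...) {
    case_record(
      subject_id = stringr::str_trim(subject_id),
      vhl_hgvs_c = na_if_empty(fmt_or_empty(vhl_hgvs_c)),
      vhl_classification = na_if_empty(fmt_or_empty(vhl_classification)),
      zygosity = normalize_term(fmt_or_empty(zygosity)),
      deleted_exons = if (is.na(deleted_exons) || !nzchar(deleted_exons))
        integer(0)
      else suppressWarnings(
        as.integer(stringr::str_split_1(deleted_exons, ","))),
      differential_findings = parse_differentials(differential_findings),
      evaluated_in_genetics = parse_bool(evaluated_in_genetics),
      age_years = if (is.na(age_years) || !nzchar(age_years)) NA_integer_
                  else suppressWarnings(as.integer(age_years)),
      sex = normalize_term(fmt_or_empty(sex)),
      personal_tumors = parse_tumors(personal_tumors),
      personal_features = normalize_term(split_list(personal_features)),
      non_vhl_tumors = split_list(non_vhl_tumors),
      family_history_vhl = normalize_term(fmt_or_empty(family_history_vhl)),
      family_degree = na_if_empty(normalize_term(fmt_or_empty(
        family_degree))),
      somatic_tested = parse_bool(somatic_tested),
      somatic = parse_somatic(somatic_alterations))
  })
}

#' @rdname read_case_table
#' @export
write_case_table <- function(cases, path) {
  flat <- tibble::tibble(
    subject_id = cases$subject_id,
    vhl_hgvs_c = fmt_or_empty(cases$vhl_hgvs_c),
    vhl_classification = fmt_or_empty(cases$vhl_classification),
    zygosity = fmt_or_empty(cases$zygosity),
    deleted_exons = purrr::map_chr(cases$deleted_exons,
                                   ~ paste(.x, collapse = ",")),
    differential_findings = purrr::map_chr(cases$differential_findings,
                                           serialize_differentials),
    evaluated_in_genetics = tolower(cases$evaluated_in_genetics),
    age_years = fmt_or_empty(cases$age_years),
    sex = fmt_or_empty(cases$sex),
    personal_tumors = purrr::map_chr(cases$personal_tumors,
                                     serialize_tumors),
    personal_features = purrr::map_chr(cases$personal_features,
                                       ~ paste(.x, collapse = ";")),
    non_vhl_tumors = purrr::map_chr(cases$non_vhl_tumors,
                                    ~ paste(.x, collapse = ";")),
    family_history_vhl = fmt_or_empty(cases$family_history_vhl),
    family_degree = fmt_or_empty(cases$family_degree),
    somatic_tested = tolower(cases$somatic_tested),
    somatic_alterations = purrr::map_chr(cases$somatic, serialize_somatic))
  readr::write_tsv(flat, path, na = "")
  invisible(path)
}

#' @rdname read_case_table
#' @export
write_cases_json <- function(cases, path) {
  objs <- purrr::map(seq_len(nrow(cases)), function(i) {
    row <- cases[i, ]
    list(
      subject_id = row$subject_id,
      vhl_hgvs_c = row$vhl_hgvs_c,
      vhl_classification = row$vhl_classification,
      zygosity = row$zygosity,
      deleted_exons = row$deleted_exons[[1]],
      differential_findings = row$differential_findings[[1]],
      evaluated_in_genetics = row$evaluated_in_genetics,
      age_years = row$age_years,
      sex = row$sex,
      personal_tumors = row$personal_tumors[[1]],
      personal_features = row$personal_features[[1]],
      non_vhl_tumors = row$non_vhl_tumors[[1]],
      family_history_vhl = row$family_history_vhl,
      family_degree = row$family_degree,
      somatic_tested = row$somatic_tested,
      somatic = row$somatic[[1]])
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, dataframe = "rows",
                       na = "null", null = "null", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname read_case_table
#' @export
read_cases_json <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(objs) == 0) return(case_record(character(0))[0, ])
  purrr::map_dfr(objs, function(o) {
    as_df <- function(x, empty) {
      if (length(x) == 0) return(empty)
      purrr::map_dfr(x, ~ tibble::as_tibble(purrr::map(.x, ~ .x %||% NA)))
    }
    tum <- as_df(o$personal_tumors, empty_tumors())
    if (nrow(tum) > 0) {
      tum <- tumor_record(tum$tumor_type, tum$laterality_count,
                          tum$sdh_deficient)
    }
    som <- as_df(o$somatic, empty_somatic())
    if (nrow(som) > 0) {
      som <- somatic_alteration(
        hgvs_c = as.character(som$hgvs_c),
        alteration_type = som$alteration_type,
        vaf_percent = som$vaf_percent, log2_ratio = som$log2_ratio,
        coverage = som$coverage, unique_reads = som$unique_reads,
        population_af_percent = som$population_af_percent,
        cosmic_count = som$cosmic_count, tumor_source = som$tumor_source)
    }
    case_record(
      subject_id = o$subject_id,
      vhl_hgvs_c = o$vhl_hgvs_c %||% NA_character_,
      vhl_classification = o$vhl_classification %||% NA_character_,
      zygosity = o$zygosity %||% "unknown",
      deleted_exons = unlist(o$deleted_exons) %||% integer(0),
      differential_findings = as_df(o$differential_findings,
                                    empty_differentials()),
      evaluated_in_genetics = isTRUE(o$evaluated_in_genetics),
      age_years = o$age_years %||% NA_integer_,
      sex = o$sex %||% "unknown",
      personal_tumors = tum,
      personal_features = unlist(o$personal_features) %||% character(0),
      non_vhl_tumors = unlist(o$non_vhl_tumors) %||% character(0),
      family_history_vhl = o$family_history_vhl %||% "unknown",
      family_degree = o$family_degree %||% NA_character_,
      somatic_tested = isTRUE(o$somatic_tested),
      somatic = som)
  })
}
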