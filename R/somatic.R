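# Somatic VHL alteration analysis: detection-limit QC, log2 copy calls,
# the presumed-somatic VAF heuristic, and allelic status (second hit vs
# biallelic LOH) from the retained alterations of one tumor profile.

#' QC-filter somatic SNV/indel records
#'
#' Applies the panel detection limits to each alteration: minimum
#' coverage, minimum VAF, minimum unique supporting reads, and a
#' population allele-frequency exclusion that a COSMIC recurrence count
#' can rescue. A record is rejected if any available metric fails; by
#' default a missing metric passes (retrospective records often lack some
#' fields) unless `cfg$strict`. Copy-number and SV records carry no SNV
#' metrics and pass through.
#'
#' @param alterations Tibble of [somatic_alteration()] rows.
#' @param cfg A [somatic_qc_config()].
#' @return `alterations` with added columns `qc_pass` (logical) and
#'   `qc_reasons` (list-column of character vectors naming the failed
#'   metrics).
#' @export
qc_filter <- function(alterations, cfg = somatic_qc_config()) {
  if (nrow(alterations) == 0) {
    alterations$qc_pass <- logical(0)
    alterations$qc_reasons <- list()
    return(alterations)
  }
  res <- purrr::pmap(alterations, function(alteration_type, vaf_percent,
                                           coverage, unique_reads,
                                           population_af_percent,
                                           cosmic_count, ...) {
    reasons <- character(0)
    if (alteration_type %in% c("snv", "indel")) {
      fail <- function(x, bad) {
        if (is.na(x)) cfg$strict else bad(x)
      }
      if (fail(coverage, function(x) x < cfg$min_coverage)) {
        reasons <- c(reasons, "coverage")
      }
      if (fail(vaf_percent, function(x) x < cfg$min_vaf_percent)) {
        reasons <- c(reasons, "vaf")
      }
      if (fail(unique_reads, function(x) x < cfg$min_unique_reads)) {
        reasons <- c(reasons, "unique_reads")
      }
      pop_fail <- fail(population_af_percent,
                       function(x) x > cfg$max_population_af_percent)
      rescued <- !is.na(cosmic_count) &&
        cosmic_count >= cfg$cosmic_rescue_min_count
      if (pop_fail && !rescued) reasons <- c(reasons, "population_af")
    }
    reasons
  })
  alterations$qc_pass <- lengths(res) == 0
  alterations$qc_reasons <- res
  alterations
}

#' Call copy-number state from a log2 ratio
#'
#' Both thresholds are inclusive: `log2_ratio >= amp_log2_min` (default
#' 0.43) is an amplification, `log2_ratio <= loss_log2_max` (default
#' -0.32) a loss, anything between neutral.
#'
#' @param log2_ratio Finite numeric (vectorized).
#' @param cfg A [copy_call_config()].
#' @return Character vector in {"amplification", "loss", "neutral"}.
#' @examples
#' call_copy(c(0.43, -0.32, 0))
#' @export
call_copy <- function(log2_ratio, cfg = copy_call_config()) {
  if (any(!is.finite(log2_ratio))) {
    stop("bad_ratio: log2_ratio must be finite")
  }
  dplyr::case_when(
    log2_ratio >= cfg$amp_log2_min ~ "amplification",
    log2_ratio <= cfg$loss_log2_max ~ "loss",
    TRUE ~ "neutral")
}

#' Presumed-somatic VAF heuristic
#'
#' In patients with no germline sequencing, a VHL alteration found by
#' tumor profiling is presumed somatic when its VAF falls outside the
#' expected heterozygous band *and* there is no clinical suspicion of VHL
#' syndrome. Without germline data this remains a presumption suitable
#' only for landscape analysis, not for case-level classification.
#'
#' @param vaf_percent VAF in percent, in \[0, 100\] (vectorized).
#' @param het_band Length-2 numeric band compatible with a heterozygous
#'   germline variant (default from [vef_config()]).
#' @param clinical_suspicion Logical (vectorized); `TRUE` blocks the
#'   presumption.
#' @return A logical vector with attribute `"rule"` recording, per
#'   element, which rule fired (`"below_band"`, `"above_band"`,
#'   `"in_band"`, `"clinical_suspicion"`).
#' @export
presumed_somatic <- function(vaf_percent,
                             het_band = vef_config()$het_vaf_band,
                             clinical_suspicion = FALSE) {
  stopifnot(all(vaf_percent >= 0 & vaf_percent <= 100, na.rm = TRUE))
  n <- max(length(vaf_percent), length(clinical_suspicion))
  vaf <- rep_len(vaf_percent, n)
  susp <- rep_len(clinical_suspicion, n)
  rule <- dplyr::case_when(
    susp ~ "clinical_suspicion",
    vaf < het_band[1] ~ "below_band",
    vaf > het_band[2] ~ "above_band",
    TRUE ~ "in_band")
  structure(rule %in% c("below_band", "above_band"), rule = rule)
}

somatic_statuses <- function() {
  c("no_inactivation", "monoallelic_second_hit_candidate", "biallelic_loh",
    "uninformative")
}

# Is one retained alteration VHL-inactivating, and how many hits does it
# represent? SNV/indels count when their effect is missense or null
# (synonymous and deep-intronic changes do not inactivate); a one-copy
# deletion is one hit, a two-copy deletion removes both alleles (two
# hits); amplifications never inactivate a tumor suppressor; SVs are not
# classifiable from the record alone.
alteration_hits <- function(hgvs_c, alteration_type) {
  if (alteration_type %in% c("snv", "indel")) {
    eff <- if (is.na(hgvs_c) || !is_parseable_cdna(hgvs_c)) "other"
           else classify_effect(hgvs_c)
    return(if (eff %in% c("missense", "null")) 1L else 0L)
  }
  switch(alteration_type,
         one_copy_deletion = 1L,
         two_copy_deletion = 2L,
         amplification = 0L,
         sv = NA_integer_,
         0L)
}

#' Somatic VHL allelic status of one tumor profile
#'
#' Classifies the QC-retained alterations of a single tumor into
#' `no_inactivation` (no inactivating event), a
#' `monoallelic_second_hit_candidate` (exactly one inactivating event —
#' the possible somatic second hit on the remaining allele of a germline
#' carrier), or `biallelic_loh` (two or more inactivating hits: SNV plus
#' copy deletion, two SNVs, or a two-copy deletion alone — the signature
#' of a sporadic tumor). Profiles with only SV or otherwise
#' unclassifiable records are `uninformative`.
#'
#' @param alterations Tibble of QC-retained [somatic_alteration()] rows
#'   for one tumor.
#' @return A list with `status` (see above) and `mechanism` (for
#'   `biallelic_loh`: `"snv_plus_deletion"`, `"two_snvs"`,
#'   `"two_copy_deletion"` or `"other"`; otherwise `NA`).
#' @export
allelic_status <- function(alterations) {
  if (nrow(alterations) == 0) {
    return(list(status = "no_inactivation", mechanism = NA_character_))
  }
  hits <- purrr::map2_int(alterations$hgvs_c, alterations$alteration_type,
                          alteration_hits)
  n_hits <- sum(hits, na.rm = TRUE)
  only_unclassifiable <- all(is.na(hits))
  if (only_unclassifiable) {
    return(list(status = "uninformative", mechanism = NA_character_))
  }
  if (n_hits == 0) {
    return(list(status = "no_inactivation", mechanism = NA_character_))
  }
  if (n_hits == 1) {
    return(list(status = "monoallelic_second_hit_candidate",
                mechanism = NA_character_))
  }
  type <- alterations$alteration_type
  inactivating <- !is.na(hits) & hits > 0
  n_snv <- sum(inactivating & type %in% c("snv", "indel"))
  n_del1 <- sum(inactivating & type == "one_copy_deletion")
  n_del2 <- sum(inactivating & type == "two_copy_deletion")
  mechanism <- if (n_del2 > 0 && n_snv == 0 && n_del1 == 0) {
    "two_copy_deletion"
  } else if (n_snv >= 1 && (n_del1 + n_del2) >= 1) {
    "snv_plus_deletion"
  } else if (n_snv >= 2) {
    "two_snvs"
  } else {
    "other"
  }
  list(status = "biallelic_loh", mechanism = mechanism)
}

#' Cohort-level somatic landscape summary
#'
#' Tabulates somatic tumor profiles by tumor type, allelic status,
#' mechanism, SNV effect class and region, after QC filtering. Profiles
#' from SDH-deficient paragangliomas are excluded from the VHL-related
#' tumor summary (their driver is SDH loss, not VHL) and reported in the
#' `n_excluded_sdh_paraganglioma` attribute.
#'
#' @param cases A validated case table; each somatic-tested case
#'   contributes one profile per distinct `tumor_source`.
#' @param cfg A [vef_config()].
#' @return A tidy tibble with columns `tumor_type`, `status`, `mechanism`,
#'   `n`, plus attributes `n_excluded_sdh_paraganglioma`,
#'   `loh_proportion` and `non_loh_proportion` (over informative
#'   profiles).
#' @export
landscape_summary <- function(cases, cfg = vef_config()) {
  profiles <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    row <- cases[i, ]
    som <- row$somatic[[1]]
    if (!row$somatic_tested || nrow(som) == 0) return(NULL)
    som <- qc_filter(som, cfg$qc)
    som <- som[som$qc_pass, ]
    if (nrow(som) == 0) return(NULL)
    sdh_pgl <- row$personal_tumors[[1]]
    sdh_types <- sdh_pgl$tumor_type[sdh_pgl$sdh_deficient]
    som$tumor_source[is.na(som$tumor_source)] <- "unknown"
    purrr::map_dfr(split(som, som$tumor_source), function(prof) {
      st <- allelic_status(prof)
      tibble::tibble(subject_id = row$subject_id,
                     tumor_type = prof$tumor_source[1],
                     excluded_sdh = prof$tumor_source[1] %in% sdh_types,
                     status = st$status,
                     mechanism = st$mechanism %||% NA_character_)
    })
  })
  if (nrow(profiles) == 0) {
    out <- tibble::tibble(tumor_type = character(0), status = character(0),
                          mechanism = character(0), n = integer(0))
    attr(out, "n_excluded_sdh_paraganglioma") <- 0L
    attr(out, "loh_proportion") <- NA_real_
    attr(out, "non_loh_proportion") <- NA_real_
    return(out)
  }
  kept <- profiles[!profiles$excluded_sdh, ]
  out <- dplyr::count(kept, .data$tumor_type, .data$status,
                      .data$mechanism, name = "n")
  informative <- kept$status != "uninformative"
  attr(out, "n_excluded_sdh_paraganglioma") <- sum(profiles$excluded_sdh)
  attr(out, "loh_proportion") <-
    if (any(informative)) mean(kept$status[informative] == "biallelic_loh")
    else NA_real_
  attr(out, "non_loh_proportion") <-
    if (any(informative)) mean(kept$status[informative] != "biallelic_loh")
    else NA_real_
  out
}
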