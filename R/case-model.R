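#' Build a tumor record
#'
#' One personal-history tumor. Bilateral tumors are entered once with
#' `laterality_count = 2` and count per laterality in the evidence vector.
#' `sdh_deficient` may be `TRUE` only for paragangliomas; SDH-deficient
#' paragangliomas are excluded from the VHL component tumor count.
#'
#' @param tumor_type One of [vhl_component_tumors()].
#' @param laterality_count Positive integer, number of independent foci
#'   counted (bilateral = 2).
#' @param sdh_deficient Logical; paraganglioma only.
#' @param age_at_dx Optional age at diagnosis in years.
#' @return A one-row tibble.
#' @export
tumor_record <- function(tumor_type, laterality_count = 1L,
                         sdh_deficient = FALSE, age_at_dx = NA_integer_) {
  tibble::tibble(
    tumor_type = as.character(tumor_type),
    laterality_count = as.integer(laterality_count),
    sdh_deficient = isTRUE(sdh_deficient),
    age_at_dx = as.integer(age_at_dx))
}

#' Build a somatic alteration record
#'
#' One somatic VHL alteration from tumor profiling. SNV/indel records carry
#' an HGVS cDNA string and (when available) VAF, coverage, unique read and
#' population-frequency metrics; copy-number records carry a log2 ratio or
#' an explicit call via `alteration_type`.
#'
#' @param alteration_type One of [somatic_alteration_types()].
#' @param hgvs_c HGVS cDNA string (snv/indel).
#' @param vaf_percent Variant allele fraction, percent (snv/indel only).
#' @param log2_ratio Normalized log2 copy ratio (copy records).
#' @param coverage Read depth at the site.
#' @param unique_reads Unique supporting reads.
#' @param population_af_percent Population allele frequency, percent.
#' @param cosmic_count Times reported in COSMIC.
#' @param tumor_source Tumor type the profile came from (component-tumor
#'   vocabulary term or free text for non-VHL tumors).
#' @return A one-row tibble.
#' @export
somatic_alteration <- function(alteration_type,
                               hgvs_c = NA_character_,
                               vaf_percent = NA_real_,
                               log2_ratio = NA_real_,
                               coverage = NA_integer_,
                               unique_reads = NA_integer_,
                               population_af_percent = NA_real_,
                               cosmic_count = NA_integer_,
                               tumor_source = NA_character_) {
  tibble::tibble(
    hgvs_c = as.character(hgvs_c),
    alteration_type = as.character(alteration_type),
    vaf_percent = as.numeric(vaf_percent),
    log2_ratio = as.numeric(log2_ratio),
    coverage = as.integer(coverage),
    unique_reads = as.integer(unique_reads),
    population_af_percent = as.numeric(population_af_percent),
    cosmic_count = as.integer(cosmic_count),
    tumor_source = as.character(tumor_source))
}

empty_tumors <- function() tumor_record(character(0))[0, ]
empty_differentials <- function() {
  tibble::tibble(gene = character(0), classification = character(0))
}
empty_somatic <- function() somatic_alteration(character(0))[0, ]

#' Build a case record
#'
#' One patient's full evidence bundle as a one-row tibble with list-columns
#' for the repeated axes (differential findings, tumors, features, somatic
#' alterations). Several cases row-bind into a case table.
#'
#' @param subject_id Opaque unique identifier.
#' @param vhl_hgvs_c Germline VHL variant, HGVS cDNA (NA when the case has
#'   no germline VHL variant).
#' @param vhl_classification Reported classification, one of
#'   [germline_classifications()] ("favor polymorphism" is normalized to LB
#'   at validation).
#' @param zygosity One of [zygosity_levels()].
#' @param deleted_exons Integer vector, subset of 1:3; non-empty marks the
#'   germline variant as a copy-number (multi-exon / whole-gene) deletion.
#' @param differential_findings Tibble with columns `gene`,
#'   `classification`; `NULL` for none.
#' @param evaluated_in_genetics Logical, evaluated at a genetics clinic.
#' @param age_years Optional age in whole years.
#' @param sex "female", "male" or "unknown".
#' @param personal_tumors Tibble of [tumor_record()] rows; `NULL` for none.
#' @param personal_features Character vector from [vhl_features()].
#' @param non_vhl_tumors Character vector of non-VHL tumor names (free
#'   text).
#' @param family_history_vhl "positive", "negative" or "unknown" for a
#'   family diagnosis of VHL syndrome.
#' @param family_degree "first", "second" or "other"; only with a positive
#'   family history, and only first/second degree meet the framework's
#'   family-history criterion.
#' @param somatic_tested Logical; `FALSE` implies no somatic records.
#' @param somatic Tibble of [somatic_alteration()] rows; `NULL` for none.
#' @return A one-row tibble (a case table of one case).
#' @examples
#' case_record("S1", vhl_hgvs_c = "c.208G>A", vhl_classification = "VUS",
#'             age_years = 16, family_history_vhl = "positive",
#'             family_degree = "first")
#' @export
case_record <- function(subject_id,
                        vhl_hgvs_c = NA_character_,
                        vhl_classification = NA_character_,
                        zygosity = "heterozygous",
                        deleted_exons = integer(0),
                        differential_findings = NULL,
                        evaluated_in_genetics = TRUE,
                        age_years = NA_integer_,
                        sex = "unknown",
                        personal_tumors = NULL,
                        personal_features = character(0),
                        non_vhl_tumors = character(0),
                        family_history_vhl = "negative",
                        family_degree = NA_character_,
                        somatic_tested = FALSE,
                        somatic = NULL) {
  tibble::tibble(
    subject_id = as.character(subject_id),
    vhl_hgvs_c = as.character(vhl_hgvs_c),
    vhl_classification = as.character(vhl_classification),
    zygosity = as.character(zygosity),
    deleted_exons = list(as.integer(deleted_exons)),
    differential_findings = list(differential_findings %||%
                                   empty_differentials()),
    evaluated_in_genetics = isTRUE(evaluated_in_genetics),
    age_years = as.integer(age_years),
    sex = as.character(sex),
    personal_tumors = list(personal_tumors %||% empty_tumors()),
    personal_features = list(as.character(personal_features)),
    non_vhl_tumors = list(as.character(non_vhl_tumors)),
    family_history_vhl = as.character(family_history_vhl),
    family_degree = as.character(family_degree),
    somatic_tested = isTRUE(somatic_tested),
    somatic = list(somatic %||% empty_somatic()))
}

case_table_columns <- function() {
  c("subject_id", "vhl_hgvs_c", "vhl_classification", "zygosity",
    "deleted_exons", "differential_findings", "evaluated_in_genetics",
    "age_years", "sex", "personal_tumors", "personal_features",
    "non_vhl_tumors", "family_history_vhl", "family_degree",
    "somatic_tested", "somatic")
}
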