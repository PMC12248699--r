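#' Controlled vocabularies
#'
#' Accessors for the controlled vocabularies the evidence model validates
#' against: the seven VHL component tumor types, the three VHL-related
#' clinical features, the thirteen differential-diagnosis genes, the
#' germline classification levels, and the scenario code set.
#'
#' @return A character vector of vocabulary terms.
#' @examples
#' vhl_component_tumors()
#' vhl_differential_genes()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
vhl_component_tumors <- function() {
  c("retinal_hemangioblastoma", "cns_hemangioblastoma", "rcc",
    "pheochromocytoma", "pancreatic_net", "endolymphatic_sac_tumor",
    "paraganglioma")
}

#' @rdname vocabularies
#' @export
vhl_features <- function() {
  c("multiple_kidney_cysts", "multiple_pancreatic_cysts",
    "epididymal_or_broad_ligament_cysts")
}

#' @rdname vocabularies
#' @export
vhl_differential_genes <- function() {
  c("FH", "FLCN", "MET", "BAP1", "SDHA", "SDHB", "SDHC", "SDHD",
    "SDHAF2", "TMEM127", "MAX", "RET", "NF1")
}

#' @rdname vocabularies
#' @export
germline_classifications <- function() {
  c("P", "LP", "VUS", "LB", "B", "P_ECYT2")
}

#' @rdname vocabularies
#' @export
zygosity_levels <- function() {
  c("heterozygous", "homozygous", "compound_heterozygous", "hemizygous",
    "unknown")
}

#' @rdname vocabularies
#' @export
somatic_alteration_types <- function() {
  c("snv", "indel", "one_copy_deletion", "two_copy_deletion",
    "amplification", "sv")
}

#' @rdname vocabularies
#' @export
vef_codes <- function() {
  c("I-I", "I-II", "I-III", "I-IV",
    "II-I", "II-II", "II-III", "II-IV", "II-V", "II-VI", "II-VII",
    "III-I", "III-II", "III-III",
    "IV-I", "IV-II", "IV-III")
}

#' @rdname vocabularies
#' @export
vef_categories <- function() {
  c("Positive", "Neutral", "Negative", "NOS")
}

# Category implied by the roman-numeral prefix of a code.
code_category <- function(code) {
  prefix <- stringr::str_extract(code, "^[IV]+")
  unname(c(I = "Positive", II = "Neutral", III = "Negative",
           IV = "NOS")[prefix])
}

# normalize a vocabulary term: trim, collapse whitespace to _, lower-case
normalize_term <- function(x) {
  x <- stringr::str_trim(x)
  x <- stringr::str_replace_all(x, "\\s+", "_")
  tolower(x)
}
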