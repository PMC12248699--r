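#' Somatic SNV/indel quality-control thresholds
#'
#' Detection limits for somatic single-nucleotide variants and indels from
#' panel tumor sequencing: minimum coverage and variant allele fraction
#' (the assay's validated limit of detection), minimum unique supporting
#' reads, a population allele-frequency exclusion, and the COSMIC
#' recurrence count that rescues a population-frequency exclusion.
#'
#' @param min_coverage Minimum read depth at the site (default 50).
#' @param min_vaf_percent Minimum variant allele fraction, percent
#'   (default 10).
#' @param min_unique_reads Minimum unique supporting reads (default 5).
#' @param max_population_af_percent Maximum population allele frequency in
#'   ESP/gnomAD, percent (default 0.1).
#' @param cosmic_rescue_min_count A variant excluded on population frequency
#'   is retained if reported in COSMIC at least this many times (default 2).
#' @param strict When `TRUE`, records missing a QC metric are rejected;
#'   by default missing metrics pass (retrospective records often lack
#'   some fields).
#' @return A list of class `somatic_qc_config`.
#' @export
somatic_qc_config <- function(min_coverage = 50,
                              min_vaf_percent = 10,
                              min_unique_reads = 5,
                              max_population_af_percent = 0.1,
                              cosmic_rescue_min_count = 2,
                              strict = FALSE) {
  stopifnot(min_coverage >= 0, min_vaf_percent >= 0, min_unique_reads >= 0,
            max_population_af_percent >= 0, cosmic_rescue_min_count >= 0)
  structure(
    list(min_coverage = min_coverage,
         min_vaf_percent = min_vaf_percent,
         min_unique_reads = min_unique_reads,
         max_population_af_percent = max_population_af_percent,
         cosmic_rescue_min_count = cosmic_rescue_min_count,
         strict = isTRUE(strict)),
    class = "somatic_qc_config")
}

#' Log2-ratio copy-number call thresholds
#'
#' Thresholds on the normalized log2 ratio of a genomic segment:
#' `>= amp_log2_min` is called an amplification (low-level gain and above),
#' `<= loss_log2_max` a copy-number loss, anything between neutral.
#' Both thresholds are inclusive.
#'
#' @param amp_log2_min Minimum log2 ratio called as amplification
#'   (default 0.43).
#' @param loss_log2_max Maximum log2 ratio called as loss (default -0.32).
#' @return A list of class `copy_call_config`.
#' @export
copy_call_config <- function(amp_log2_min = 0.43, loss_log2_max = -0.32) {
  stopifnot(is.finite(amp_log2_min), is.finite(loss_log2_max),
            loss_log2_max < 0, amp_log2_min > 0)
  structure(list(amp_log2_min = amp_log2_min, loss_log2_max = loss_log2_max),
            class = "copy_call_config")
}

#' Framework configuration
#'
#' Tunable parameters of the evidence framework that sit outside the
#' scenario table itself.
#'
#' @param age_young_threshold Age in whole years below which a proband is
#'   binned as "young" for the age-related penetrance scenarios
#'   (default 30; mean ages at diagnosis of the component tumors span
#'   roughly 22-39 years).
#' @param het_vaf_band Length-2 numeric, the variant-allele-fraction band
#'   (percent) treated as compatible with a heterozygous germline variant;
#'   VAFs outside it support a presumed-somatic origin (default c(40, 60)).
#' @param qc A [somatic_qc_config()].
#' @param copy A [copy_call_config()].
#' @return A list of class `vef_config`.
#' @export
vef_config <- function(age_young_threshold = 30,
                       het_vaf_band = c(40, 60),
                       qc = somatic_qc_config(),
                       copy = copy_call_config()) {
  stopifnot(age_young_threshold > 0, length(het_vaf_band) == 2,
            het_vaf_band[1] < het_vaf_band[2],
            inherits(qc, "somatic_qc_config"),
            inherits(copy, "copy_call_config"))
  structure(
    list(age_young_threshold = age_young_threshold,
         het_vaf_band = het_vaf_band, qc = qc, copy = copy),
    class = "vef_config")
}
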