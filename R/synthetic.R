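# Deterministic synthetic case-table generator. Generation is
# scenario-first: each case draws its target scenario code from the
# requested mix (by exact largest-remainder apportionment, so encoding a
# generated cohort recovers the mix exactly), is constructed to satisfy
# that scenario's predicate, and is then decorated with a plausible VHL
# variant, classification, sex and age. The intended code is returned as
# a truth label per row.

somatic_gated_codes <- function() {
  c("I-II", "I-III", "II-I", "II-II", "II-III", "III-I")
}

# decoration pool: recurrent germline VHL variants reported in the
# clinical literature (SNVs, indels, deep-intronic E1' variants)
variant_pool <- function() {
  c("c.208G>A", "c.345C>A", "c.532C>G", "c.292T>C", "c.562C>G",
    "c.388G>A", "c.429C>T", "c.341-1G>A", "c.464-1G>C",
    "c.506_509delinsCG", "c.217C>T", "c.123_137del", "c.25G>A",
    "c.340+705G>A", "c.613C>T", "c.340+691C>G", "c.340+742G>T",
    "c.3G>A", "c.631A>C", "c.340+694_340+711dup", "c.545G>A",
    "c.598C>T", "c.5C>T", "c.626A>G", "c.340+578C>T", "c.227_229del",
    "c.371C>T")
}

#' Specify a synthetic cohort
#'
#' @param n_cases Number of cases to generate.
#' @param seed Integer seed; the same spec and seed generate
#'   byte-identical output.
#' @param scenario_mix Named numeric vector of proportions over scenario
#'   codes (default uniform over all 17); must sum to 1.
#' @param classification_mix Named proportions over reported germline
#'   classifications (default mirrors a clinical cohort dominated by
#'   VUS).
#' @param somatic_fraction For scenarios that do not themselves constrain
#'   somatic data, the fraction of cases additionally marked somatic
#'   tested (with no VHL-inactivating finding).
#' @param age_range_young,age_range_adult Uniform age ranges (years) for
#'   the young and adult bands.
#' @param female_fraction Sex ratio.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 100L, seed = 1L,
                        scenario_mix = NULL,
                        classification_mix = c(P = 0.08, LP = 0.07,
                                               VUS = 0.60, LB = 0.06,
                                               B = 0.12, P_ECYT2 = 0.07),
                        somatic_fraction = 0.2,
                        age_range_young = c(10L, 29L),
                        age_range_adult = c(30L, 80L),
                        female_fraction = 0.74) {
  scenario_mix <- scenario_mix %||%
    stats::setNames(rep(1 / 17, 17), vef_codes())
  stopifnot(n_cases >= 0, all(names(scenario_mix) %in% vef_codes()),
            all(scenario_mix >= 0), all(classification_mix >= 0),
            somatic_fraction >= 0, somatic_fraction <= 1)
  if (abs(sum(scenario_mix) - 1) > 1e-9) {
    stop("scenario_mix proportions must sum to 1")
  }
  if (abs(sum(classification_mix) - 1) > 1e-9) {
    stop("classification_mix proportions must sum to 1")
  }
  if (somatic_fraction == 0 &&
      any(scenario_mix[intersect(names(scenario_mix),
                                 somatic_gated_codes())] > 0)) {
    stop("infeasible_spec: somatic-gated scenario requested with ",
         "somatic_fraction = 0")
  }
  structure(
    list(n_cases = as.integer(n_cases), seed = as.integer(seed),
         scenario_mix = scenario_mix,
         classification_mix = classification_mix,
         somatic_fraction = somatic_fraction,
         age_range_young = as.integer(age_range_young),
         age_range_adult = as.integer(age_range_adult),
         female_fraction = female_fraction),
    class = "cohort_spec")
}

# exact largest-remainder apportionment of n among proportions
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# somatic profile helpers; metrics comfortably above detection limits
som_single_hit <- function(source) {
  somatic_alteration("snv", hgvs_c = "c.506_509delinsCG",
                     vaf_percent = 32, coverage = 220, unique_reads = 28,
                     population_af_percent = 0, tumor_source = source)
}
som_biallelic <- function(source) {
  dplyr::bind_rows(
    som_single_hit(source),
    somatic_alteration("one_copy_deletion", log2_ratio = -0.85,
                       tumor_source = source))
}

# construct one case guaranteed to satisfy the target scenario; `young`
# and `adult` are pre-drawn ages, `extra_somatic` applies only where the
# scenario leaves somatic data unconstrained
make_case_for_code <- function(code, id, hgvs, germ_class, sex, young,
                               adult, extra_somatic) {
  base <- function(..., age = adult) {
    case_record(subject_id = id, vhl_hgvs_c = hgvs,
                vhl_classification = germ_class, sex = sex,
                age_years = age, ...)
  }
  free_somatic <- function(rec) {
    # somatic testing that found no VHL-inactivating event; changes no
    # scenario that leaves somatic status unconstrained
    if (extra_somatic) rec$somatic_tested <- TRUE
    rec
  }
  hb2 <- dplyr::bind_rows(tumor_record("cns_hemangioblastoma"),
                          tumor_record("retinal_hemangioblastoma"))
  hb_rcc <- dplyr::bind_rows(tumor_record("cns_hemangioblastoma"),
                             tumor_record("rcc"))
  switch(code,
    "I-I" = free_somatic(base(personal_tumors = hb2)),
    "I-II" = base(personal_tumors = hb_rcc, somatic_tested = TRUE,
                  somatic = som_single_hit("rcc")),
    "I-III" = base(personal_tumors = tumor_record("pheochromocytoma"),
                   family_history_vhl = "positive",
                   family_degree = "first", somatic_tested = TRUE,
                   somatic = som_single_hit("pheochromocytoma")),
    "I-IV" = base(personal_tumors = dplyr::bind_rows(
                    tumor_record("rcc", laterality_count = 2),
                    tumor_record("cns_hemangioblastoma")),
                  family_history_vhl = "positive",
                  family_degree = "second"),
    "II-I" = base(personal_tumors = hb_rcc, somatic_tested = TRUE,
                  somatic = som_biallelic("rcc")),
    "II-II" = base(personal_tumors = tumor_record("cns_hemangioblastoma"),
                   somatic_tested = TRUE,
                   somatic = som_single_hit("cns_hemangioblastoma")),
    "II-III" = base(personal_tumors = tumor_record("rcc"),
                    somatic_tested = TRUE,
                    somatic = som_single_hit("rcc")),
    "II-IV" = base(personal_tumors = tumor_record("rcc",
                                                  laterality_count = 2)),
    "II-V" = base(personal_tumors = tumor_record("pheochromocytoma"),
                  age = young),
    "II-VI" = free_somatic(base(family_history_vhl = "positive",
                                family_degree = "first", age = young)),
    "II-VII" = base(personal_tumors = tumor_record("rcc",
                                                   laterality_count = 2),
                    age = young),
    "III-I" = base(personal_tumors = tumor_record("rcc"),
                   somatic_tested = TRUE, somatic = som_biallelic("rcc")),
    "III-II" = free_somatic(base(non_vhl_tumors = "breast cancer")),
    "III-III" = free_somatic(base()),
    "IV-I" = base(zygosity = "compound_heterozygous"),
    "IV-II" = base(personal_tumors = tumor_record("cns_hemangioblastoma")),
    "IV-III" = base(personal_tumors = tumor_record("pheochromocytoma"),
                    differential_findings = tibble::tibble(
                      gene = "SDHB", classification = "P")),
    stop("unknown scenario code: ", code))
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list with `cases` (a case table of `n_cases` rows, every row
#'   passing [validate_cases()]) and `truth` (a tibble `subject_id`,
#'   `true_code` with the scenario each case was constructed to satisfy).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_cases = 17, seed = 7))
#' table(cohort$truth$true_code)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_cases == 0) {
    return(list(cases = case_record(character(0))[0, ],
                truth = tibble::tibble(subject_id = character(0),
                                       true_code = character(0))))
  }
  counts <- apportion(spec$n_cases, spec$scenario_mix)
  codes <- rep(names(spec$scenario_mix), counts)
  withr::with_seed(spec$seed, {
    classes <- sample(names(spec$classification_mix), spec$n_cases,
                      replace = TRUE, prob = spec$classification_mix)
    hgvs <- sample(variant_pool(), spec$n_cases, replace = TRUE)
    sexes <- ifelse(stats::runif(spec$n_cases) < spec$female_fraction,
                    "female", "male")
    youngs <- sample(seq(spec$age_range_young[1], spec$age_range_young[2]),
                     spec$n_cases, replace = TRUE)
    adults <- sample(seq(spec$age_range_adult[1], spec$age_range_adult[2]),
                     spec$n_cases, replace = TRUE)
    extra <- stats::runif(spec$n_cases) < spec$somatic_fraction
    codes <- sample(codes)  # shuffle scenario order across the cohort
  })
  ids <- sprintf("SYN-%04d", seq_len(spec$n_cases))
  cases <- purrr::map_dfr(seq_len(spec$n_cases), function(i) {
    make_case_for_code(codes[i], ids[i], hgvs[i], classes[i], sexes[i],
                       youngs[i], adults[i], extra[i])
  })
  list(cases = cases,
       truth = tibble::tibble(subject_id = ids, true_code = codes))
}

#' Packaged worked-example fixtures
#'
#' Small hand-written case tables reproducing the published worked
#' examples: `"patients_21_23"` (one case with only a first-degree
#' family history, classified II-VI, and two single-tumor cases
#' classified IV-II), `"portal_c340+578"` (seven unrelated carriers of
#' the deep-intronic c.340+578C>T variant: four with no tumors, III-III,
#' and three with only non-VHL tumors, III-II), `"ecyt2_carriers"`
#' (heterozygous carriers of erythrocytosis-associated pathogenic
#' variants with no VHL evidence), and `"mixed_demo"` (a small
#' demonstration cohort spanning all four categories).
#'
#' @param name Fixture name.
#' @return A case table.
#' @export
vef_fixture <- function(name = c("patients_21_23", "portal_c340+578",
                                 "ecyt2_carriers", "mixed_demo")) {
  name <- match.arg(name)
  path <- system.file("extdata", "fixtures", paste0(name, ".tsv"),
                      package = "vhlvef", mustWork = TRUE)
  read_case_table(path)
}
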