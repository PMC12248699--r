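test_that("qc_filter applies the detection limits and the COSMIC rescue", {
  low_cov <- somatic_alteration("snv", hgvs_c = "c.292T>C",
                                vaf_percent = 20, coverage = 49,
                                unique_reads = 10,
                                population_af_percent = 0)
  out <- qc_filter(low_cov)
  expect_false(out$qc_pass)
  expect_identical(out$qc_reasons[[1]], "coverage")

  rescued <- somatic_alteration("snv", hgvs_c = "c.292T>C",
                                vaf_percent = 30, coverage = 200,
                                unique_reads = 20,
                                population_af_percent = 0.2,
                                cosmic_count = 3)
  expect_true(qc_filter(rescued)$qc_pass)
  not_rescued <- dplyr::mutate(rescued, cosmic_count = 1L)
  expect_identical(qc_filter(not_rescued)$qc_reasons[[1]],
                   "population_af")

  empty <- qc_filter(passing_snv()[0, ])
  expect_identical(nrow(empty), 0L)

  # missing metrics pass by default, fail in strict mode
  sparse <- somatic_alteration("snv", hgvs_c = "c.292T>C")
  expect_true(qc_filter(sparse)$qc_pass)
  expect_false(qc_filter(sparse, somatic_qc_config(strict = TRUE))$qc_pass)
})

test_that("qc_filter is monotone under threshold tightening", {
  set.seed(42)
  recs <- purrr::map_dfr(1:60, function(i) {
    somatic_alteration("snv", hgvs_c = "c.292T>C",
                       vaf_percent = stats::runif(1, 0, 60),
                       coverage = sample(10:400, 1),
                       unique_reads = sample(0:40, 1),
                       population_af_percent = stats::runif(1, 0, 0.4),
                       cosmic_count = sample(c(NA, 0:4), 1))
  })
  base_cfg <- somatic_qc_config()
  base <- qc_filter(recs, base_cfg)$qc_pass
  tighter <- list(
    somatic_qc_config(min_coverage = 100),
    somatic_qc_config(min_vaf_percent = 20),
    somatic_qc_config(min_unique_reads = 10),
    somatic_qc_config(max_population_af_percent = 0.05),
    somatic_qc_config(cosmic_rescue_min_count = 4))
  for (cfg in tighter) {
    expect_true(all(qc_filter(recs, cfg)$qc_pass <= base))
  }
})

test_that("copy calls are closed at both thresholds", {
  expect_identical(call_copy(c(0.43, 0.44, 5)),
                   rep("amplification", 3))
  expect_identical(call_copy(c(-0.32, -0.33, -3)), rep("loss", 3))
  expect_identical(call_copy(c(0, 0.42, -0.31, 0.4299)),
                   rep("neutral", 4))
  expect_error(call_copy(NaN), "bad_ratio")
  expect_error(call_copy(Inf), "bad_ratio")
})

test_that("presumed-somatic rule fires only out of band without suspicion", {
  expect_true(presumed_somatic(27))
  expect_false(presumed_somatic(50))
  expect_false(presumed_somatic(68, clinical_suspicion = TRUE))
  expect_true(presumed_somatic(68))
  r <- presumed_somatic(c(27, 50, 68), clinical_suspicion = c(FALSE, FALSE,
                                                              TRUE))
  expect_identical(attr(r, "rule"),
                   c("below_band", "in_band", "clinical_suspicion"))
  # band edges are inside the heterozygous band
  expect_false(presumed_somatic(40))
  expect_false(presumed_somatic(60))
})

test_that("allelic status matches a brute-force oracle over all multisets", {
  kinds <- c("missense_snv", "null_snv", "one_copy_deletion",
             "two_copy_deletion", "amplification", "sv")
  for (ms in all_multisets(kinds, 3)) {
    alt <- purrr::map_dfr(ms, kind_to_alteration)
    if (length(ms) == 0) alt <- passing_snv()[0, ]
    got <- allelic_status(alt)
    expect_identical(got$status, oracle_allelic(ms),
                     info = paste(ms, collapse = "+"))
    expect_identical(got$status == "biallelic_loh", !is.na(got$mechanism))
  }
})

test_that("LOH mechanisms are labeled by event combination", {
  expect_identical(
    allelic_status(dplyr::bind_rows(passing_snv("rcc", "c.292T>C"),
                                    copy_loss()))$mechanism,
    "snv_plus_deletion")
  expect_identical(
    allelic_status(copy_loss(type = "two_copy_deletion"))$mechanism,
    "two_copy_deletion")
  expect_identical(
    allelic_status(dplyr::bind_rows(
      passing_snv("rcc", "c.292T>C"),
      passing_snv("rcc", "c.341-1G>A")))$mechanism,
    "two_snvs")
  expect_identical(
    allelic_status(passing_snv())$status,
    "monoallelic_second_hit_candidate")
  # a synonymous SNV does not inactivate
  expect_identical(
    allelic_status(passing_snv("rcc", "c.429C>T"))$status,
    "no_inactivation")
})

test_that("landscape summary counts profiles and excludes SDH paragangliomas", {
  mk <- function(id, som, tumors = tumor_record("rcc")) {
    case_record(id, vhl_hgvs_c = "c.292T>C", personal_tumors = tumors,
                somatic_tested = TRUE, somatic = som)
  }
  cohort <- dplyr::bind_rows(
    mk("R1", som = dplyr::bind_rows(passing_snv(), copy_loss())),
    mk("R2", som = dplyr::bind_rows(passing_snv("rcc", "c.341-1G>A"),
                                    copy_loss())),
    mk("R3", som = passing_snv()),
    mk("R4", som = passing_snv("rcc", "c.341-1G>A")),
    mk("PG", som = passing_snv("paraganglioma"),
       tumors = tumor_record("paraganglioma", sdh_deficient = TRUE)))
  summ <- landscape_summary(validate_cases(cohort))
  expect_equal(attr(summ, "loh_proportion"), 0.5)
  expect_equal(attr(summ, "non_loh_proportion"), 0.5)
  expect_identical(attr(summ, "n_excluded_sdh_paraganglioma"), 1L)
  # conservation: profiles in = counted + excluded
  expect_identical(sum(summ$n) + attr(summ, "n_excluded_sdh_paraganglioma"),
                   5L)
  empty <- landscape_summary(validate_cases(hb_case()[0, ]))
  expect_identical(nrow(empty), 0L)
})
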