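test_that("a complete clinical record validates cleanly", {
  p21 <- case_record("P21", vhl_hgvs_c = "c.208G>A",
                     vhl_classification = "VUS", age_years = 16,
                     sex = "female", family_history_vhl = "positive",
                     family_degree = "first")
  v <- validate_cases(p21)
  expect_true(v$.valid)
  expect_equal(nrow(case_issues(v)), 0L)
})

test_that("invariant violations are reported with a reason each", {
  bad_sdh <- case_record("A", vhl_hgvs_c = "c.292T>C",
                         personal_tumors = tumor_record(
                           "rcc", sdh_deficient = TRUE))
  v <- validate_cases(bad_sdh)
  expect_false(v$.valid)
  expect_match(unlist(v$.issues), "sdh_deficient", all = FALSE)

  bad_deg <- case_record("B", vhl_hgvs_c = "c.292T>C",
                         family_history_vhl = "negative",
                         family_degree = "first")
  expect_match(unlist(validate_cases(bad_deg)$.issues),
               "family_degree present only when", all = FALSE)

  bad_term <- case_record("C", vhl_hgvs_c = "c.292T>C",
                          personal_tumors = tumor_record("lung adeno"))
  expect_match(unlist(validate_cases(bad_term)$.issues),
               "unknown_term", all = FALSE)

  bad_hgvs <- case_record("D", vhl_hgvs_c = "p.Tyr98His")
  expect_match(unlist(validate_cases(bad_hgvs)$.issues), "bad_hgvs",
               all = FALSE)

  dup <- dplyr::bind_rows(hb_case("X"), hb_case("X"))
  expect_match(unlist(validate_cases(dup)$.issues), "duplicate_subject",
               all = FALSE)
  expect_error(validate_cases(dup, strict = TRUE), "duplicate_subject")
})

test_that("vocabulary normalization is case- and whitespace-insensitive", {
  messy <- case_record("S1", vhl_hgvs_c = "c.292T>C",
                       vhl_classification = "favor polymorphism",
                       zygosity = " Heterozygous ",
                       family_history_vhl = "Positive",
                       family_degree = "First")
  v <- validate_cases(messy)
  expect_true(v$.valid)
  expect_identical(v$vhl_classification, "LB")
  expect_identical(v$zygosity, "heterozygous")
  expect_identical(v$family_degree, "first")
})

test_that("validation is idempotent", {
  v1 <- validate_cases(vef_fixture("mixed_demo"))
  v2 <- validate_cases(v1)
  expect_identical(v1, v2)
})

test_that("packaged vocabularies match the framework definition", {
  expect_length(vhl_component_tumors(), 7)
  expect_length(vhl_features(), 3)
  expect_length(vhl_differential_genes(), 13)
  expect_setequal(c("SDHB", "FH", "FLCN", "MET", "BAP1", "RET", "NF1"),
                  intersect(c("SDHB", "FH", "FLCN", "MET", "BAP1", "RET",
                              "NF1"), vhl_differential_genes()))
  expect_length(vef_codes(), 17)
})

test_that("case tables round-trip through TSV and JSON", {
  cases <- validate_cases(vef_fixture("mixed_demo")) |>
    dplyr::select(-".valid", -".issues")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_case_table(cases, tsv)
  back <- read_case_table(tsv)
  expect_equal(validate_cases(back) |>
                 dplyr::select(-".valid", -".issues"), cases)

  js <- withr::local_tempfile(fileext = ".json")
  write_cases_json(cases, js)
  back2 <- read_cases_json(js)
  expect_equal(validate_cases(back2) |>
                 dplyr::select(-".valid", -".issues"), cases)
})
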