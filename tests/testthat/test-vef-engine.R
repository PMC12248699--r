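test_that("eligibility gate enforces zygosity, differentials and evaluation", {
  ok <- validate_cases(hb_case())
  expect_true(gate(ok)$eligible)

  ch <- validate_cases(hb_case(zygosity = "compound_heterozygous"))
  expect_identical(gate(ch)$gate_reason, "non_heterozygous")
  hom <- validate_cases(hb_case(zygosity = "homozygous"))
  expect_identical(gate(hom)$gate_reason, "non_heterozygous")

  dif <- validate_cases(hb_case(differential_findings = tibble::tibble(
    gene = "SDHB", classification = "P")))
  expect_identical(gate(dif)$gate_reason, "differential_positive")
  # a VUS differential finding does not gate the case out
  dif_vus <- validate_cases(hb_case(differential_findings = tibble::tibble(
    gene = "SDHB", classification = "VUS")))
  expect_true(gate(dif_vus)$eligible)

  none <- validate_cases(case_record("N1"))
  expect_identical(gate(none)$gate_reason, "no_germline_variant")
  # germline whole-gene deletion counts as a variant
  del <- validate_cases(case_record("N2", deleted_exons = 1:3))
  expect_true(gate(del)$eligible)

  uneval <- validate_cases(hb_case(evaluated_in_genetics = FALSE))
  expect_identical(gate(uneval)$gate_reason, "not_evaluated")
})

test_that("evidence vectors count tumors per laterality and exclude SDH", {
  p21 <- validate_cases(vef_fixture("patients_21_23"))[1, ]
  v <- derive_vector(p21)
  expect_equal(v$n_vhl_tumors, 0L)
  expect_false(v$has_vhl_feature)
  expect_identical(v$family_history, "positive")
  expect_identical(v$age_band, "young")

  multi <- validate_cases(case_record(
    "M", vhl_hgvs_c = "c.464-1G>C",
    personal_tumors = dplyr::bind_rows(
      tumor_record("cns_hemangioblastoma"),
      tumor_record("rcc", laterality_count = 2))))
  v <- derive_vector(multi)
  expect_equal(v$n_vhl_tumors, 3L)
  expect_equal(v$n_rcc, 2L)

  sdh <- validate_cases(case_record(
    "S", vhl_hgvs_c = "c.292T>C",
    personal_tumors = tumor_record("paraganglioma",
                                   sdh_deficient = TRUE)))
  expect_equal(derive_vector(sdh)$n_vhl_tumors, 0L)

  # third-degree family diagnosis does not meet the criterion
  far <- validate_cases(hb_case(family_history_vhl = "positive",
                                family_degree = "other"))
  expect_identical(derive_vector(far)$family_history, "negative")

  # somatic status comes from the component-tumor profile
  no_som <- derive_vector(validate_cases(hb_case()))
  expect_identical(no_som$somatic_status, "uninformative")
  expect_false(no_som$somatic_available)
})

test_that("the default scenario table is total, disjoint and consistent", {
  table <- load_scenario_table()
  expect_s3_class(table, "scenario_table")
  expect_setequal(unique(table$rules$code), vef_codes())

  space <- vhlvef:::enumerate_vector_space()
  expect_gt(nrow(space), 1000)
  cls <- classify_vector(space, table)
  # totality without the fallback, i.e. every vector matched a real rule
  expect_false(anyNA(cls$matched_rule_id))
  # category always follows the code's roman prefix
  prefix_cat <- c(I = "Positive", II = "Neutral", III = "Negative",
                  IV = "NOS")
  expect_identical(cls$vef_category,
                   unname(prefix_cat[sub("-.*", "", cls$vef_code)]))

  # a broken table is rejected at load
  broken <- table
  broken$rules <- broken$rules[broken$rules$id != "r23", ]
  expect_error(validate_scenario_table(broken), "table_invalid")
  overlapping <- table
  overlapping$rules$when[[which(overlapping$rules$id == "r22")]] <-
    list(eligible = TRUE, n_vhl_tumors = 0)
  expect_error(validate_scenario_table(overlapping), "table_invalid")
})

test_that("somatic-gated codes are unreachable without somatic data", {
  gated <- c("I-II", "I-III", "II-I", "II-II", "II-III", "III-I")
  space <- vhlvef:::enumerate_vector_space()
  cls <- classify_vector(space)
  expect_true(all(space$somatic_available[cls$vef_code %in% gated]))
})

test_that("no case without tumors, features or family history is Positive", {
  space <- vhlvef:::enumerate_vector_space()
  bare <- space$n_vhl_tumors == 0 & !space$has_vhl_feature &
    space$family_history != "positive"
  cls <- classify_vector(space[bare, ])
  expect_false(any(cls$vef_category == "Positive"))
})

test_that("classification reproduces the published worked examples", {
  table <- load_scenario_table()
  fx <- validate_cases(vef_fixture("patients_21_23"))
  cls <- classify_vector(derive_vectors(fx), table)
  expect_identical(cls$vef_code, c("II-VI", "IV-II", "IV-II"))
  expect_identical(cls$vef_category, c("Neutral", "NOS", "NOS"))

  # no tumors at all vs only non-VHL tumors, adult, negative history
  iii3 <- derive_vector(validate_cases(case_record(
    "A", vhl_hgvs_c = "c.340+578C>T", age_years = 55)))
  expect_identical(classify_vector(iii3, table)$vef_code, "III-III")
  iii2 <- derive_vector(validate_cases(case_record(
    "B", vhl_hgvs_c = "c.340+578C>T", age_years = 55,
    non_vhl_tumors = "breast cancer")))
  expect_identical(classify_vector(iii2, table)$vef_code, "III-II")

  # two non-RCC component tumors: Positive I-I
  i1 <- derive_vector(validate_cases(case_record(
    "C", vhl_hgvs_c = "c.341-1G>A",
    personal_tumors = dplyr::bind_rows(
      tumor_record("cns_hemangioblastoma"),
      tumor_record("retinal_hemangioblastoma")),
    age_years = 40)))
  cls <- classify_vector(i1, table)
  expect_identical(cls$vef_code, "I-I")
  expect_identical(cls$vef_category, "Positive")
})

test_that("classification is deterministic and order-independent", {
  case <- validate_cases(case_record(
    "D", vhl_hgvs_c = "c.464-1G>C",
    personal_tumors = dplyr::bind_rows(
      tumor_record("rcc"), tumor_record("cns_hemangioblastoma")),
    somatic_tested = TRUE,
    somatic = dplyr::bind_rows(copy_loss(), passing_snv()),
    age_years = 45))
  flipped <- case
  flipped$personal_tumors <- list(case$personal_tumors[[1]][2:1, ])
  flipped$somatic <- list(case$somatic[[1]][2:1, ])
  c1 <- classify_vector(derive_vector(case))
  c2 <- classify_vector(derive_vector(flipped))
  expect_identical(c1$vef_code, c2$vef_code)
  expect_identical(c1$vef_code, "II-I")  # biallelic loss: not a second hit
})
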