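test_that("variant keys normalize prefix, case and whitespace", {
  expect_identical(normalize_variant_key("VHL: c.340+578c>t"),
                   "c.340+578C>T")
  expect_identical(normalize_variant_key("c.506_509DELINScg"),
                   "c.506_509delinsCG")
  expect_identical(
    normalize_variant_key(NA_character_, deleted_exons = list(c(3, 1, 2))),
    "del_exons_1-2-3")
})

test_that("recurrence counts distinct subjects in the portal fixture", {
  enc <- encode_cases(vef_fixture("portal_c340+578"))
  expect_equal(variant_recurrence(enc, "c.340+578C>T"), 7)
  expect_equal(variant_recurrence(enc, "VHL:c.340+578c>t"), 7)
  expect_equal(variant_recurrence(enc, "c.1A>G"), 0)

  # duplicate rows for one subject contribute once
  dup <- tidy(enc)
  expect_equal(variant_recurrence(dplyr::bind_rows(dup, dup[1, ]),
                                  "c.340+578C>T"), 7)
})

test_that("unique patterns reproduce the portal worked example", {
  s <- unique_patterns(encode_cases(vef_fixture("portal_c340+578")),
                       "c.340+578C>T")
  expect_equal(s$recurrence, 7)
  expect_equal(nrow(s$patterns), 2)
  expect_identical(s$patterns$vef_code, c("III-III", "III-II"))
  expect_identical(s$patterns$count, c(4L, 3L))
  expect_equal(sum(s$patterns$count), s$recurrence)
})

test_that("pattern counts agree with a pairwise group-by oracle", {
  cohort <- generate_cohort(cohort_spec(n_cases = 85, seed = 23))
  enc <- tidy(encode_cases(cohort$cases))
  keys <- unique(vhlvef:::encoded_with_keys(enc)$variant_key)
  for (k in keys) {
    s <- unique_patterns(enc, k)
    # oracle: linear scan with pairwise string comparison, no grouping
    df <- vhlvef:::encoded_with_keys(enc)
    rows <- df[!is.na(df$variant_key) & df$variant_key == k, ]
    rows <- rows[!duplicated(rows$subject_id), ]
    expect_equal(s$recurrence, nrow(rows))
    seen <- character(0)
    counts <- integer(0)
    for (p in rows$evidence_pattern) {
      hit <- which(vapply(seen, identical, logical(1), p))
      if (length(hit) == 0) {
        seen <- c(seen, p)
        counts <- c(counts, 1L)
      } else {
        counts[hit] <- counts[hit] + 1L
      }
    }
    expect_equal(sum(s$patterns$count), sum(counts))
    expect_setequal(paste(s$patterns$pattern, s$patterns$count),
                    paste(seen, counts))
  }
})

test_that("pattern output is independent of row order", {
  cohort <- generate_cohort(cohort_spec(n_cases = 60, seed = 31))
  enc <- tidy(encode_cases(cohort$cases))
  perm <- withr::with_seed(9, sample(nrow(enc)))
  q1 <- quantify_patterns(enc)
  q2 <- quantify_patterns(enc[perm, ])
  expect_equal(q1, q2)
})

test_that("pattern canonicalization separates differing vectors only", {
  v1 <- derive_vector(validate_cases(hb_case("A")))
  v2 <- derive_vector(validate_cases(hb_case("B")))
  v3 <- derive_vector(validate_cases(hb_case(
    "C", family_history_vhl = "positive", family_degree = "first")))
  expect_identical(evidence_pattern(v1), evidence_pattern(v2))
  expect_false(evidence_pattern(v1) == evidence_pattern(v3))
})
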