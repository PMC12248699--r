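test_that("cDNA parsing handles the clinical dialect", {
  p <- parse_cdna("c.340+578C>T")
  expect_equal(p[c("kind", "start", "start_offset", "ref", "alt")],
               list(kind = "substitution", start = 340L,
                    start_offset = 578L, ref = "C", alt = "T"))
  p <- parse_cdna("c.341-1G>A")
  expect_equal(p$start, 341L)
  expect_equal(p$start_offset, -1L)
  p <- parse_cdna("c.506_509delinsCG")
  expect_equal(p[c("kind", "start", "end", "alt")],
               list(kind = "delins", start = 506L, end = 509L, alt = "CG"))
  p <- parse_cdna("c.340+694_340+711dup")
  expect_equal(p$kind, "dup")
  expect_equal(p$end_offset, 711L)
  expect_equal(parse_cdna("VHL: c.292 T>C")$start, 292L)

  expect_error(parse_cdna("p.Tyr98His"), "bad_hgvs")
  expect_error(parse_cdna("c.nonsense"), "bad_hgvs")
  expect_error(parse_cdna("g.10183767T>C"), "bad_hgvs")
})

test_that("region mapping partitions positions and places E1prime", {
  # every deep-intron-1 variant named in the erythrocytosis literature
  e1p <- c("c.340+578C>T", "c.340+691C>G", "c.340+694_340+711dup",
           "c.340+705G>A", "c.340+742G>T")
  for (h in e1p) expect_identical(map_region(h), "intron1_E1prime")

  expect_identical(map_region("c.292T>C"), "exon1")
  expect_identical(map_region("c.1A>G"), "exon1")
  expect_identical(map_region("c.340G>A"), "exon1")
  expect_identical(map_region("c.341-1G>A"), "intron1")
  expect_identical(map_region("c.345C>A"), "exon2")
  expect_identical(map_region("c.463+2T>C"), "intron2")
  expect_identical(map_region("c.464-1G>C"), "intron2")
  expect_identical(map_region("c.642G>A"), "exon3")
  expect_identical(map_region("c.*5G>A"), "other")
  expect_identical(deletion_region(1:3), "whole_gene_deletion")
  expect_identical(deletion_region(c(1, 2)), "multi_exon_deletion")

  # partition property: each parseable position maps to exactly one region
  positions <- c(sprintf("c.%dA>G", c(1, 100, 340, 341, 463, 464, 642)),
                 sprintf("c.340+%dC>T", c(1, 2, 399, 400, 800, 801)),
                 sprintf("c.341-%dC>T", c(1, 2, 50)), e1p)
  all_regions <- c("exon1", "intron1", "intron1_E1prime", "exon2",
                   "intron2", "exon3", "multi_exon_deletion",
                   "whole_gene_deletion", "other")
  regions <- vapply(positions, map_region, character(1))
  expect_true(all(regions %in% all_regions))
  expect_true(all(lengths(lapply(positions, map_region)) == 1))
})

test_that("effect classification follows structural rules", {
  # null variants: canonical splice, frameshifting delins, nonsense
  for (h in c("c.341-1G>A", "c.464-1G>C", "c.506_509delinsCG",
              "c.217C>T")) {
    expect_identical(classify_effect(h), "null")
  }
  expect_identical(classify_effect("c.429C>T"), "synonymous")
  expect_identical(classify_effect("c.429C>T", "p.Asp143="), "synonymous")
  expect_identical(classify_effect("c.292T>C", "p.(Tyr98His)"), "missense")
  expect_identical(classify_effect("c.292T>C"), "missense")  # curated p.
  expect_identical(classify_effect("c.340+578C>T"), "intronic")
  expect_identical(classify_effect("c.3G>A"), "null")  # start codon
  expect_identical(classify_effect("c.123_137del"), "other")  # in-frame
  expect_identical(classify_effect(deleted_exons = 1:3), "copy_deletion")
  expect_identical(classify_effect("c.76dupA"), "null")  # frameshift dup

  # formatting invariance
  expect_identical(classify_effect("VHL:c.292T>C", " p.(Tyr98His) "),
                   classify_effect("c.292T>C", "p.Tyr98His"))
  expect_error(classify_effect("c.340+578C>T", "p.Tyr98His"),
               "annotation_conflict")
})

test_that("annotate_variants appends region and effect columns", {
  df <- tibble::tibble(
    vhl_hgvs_c = c("c.340+578C>T", "c.292T>C", NA),
    deleted_exons = list(integer(0), integer(0), 1:3))
  out <- annotate_variants(df)
  expect_identical(out$region,
                   c("intron1_E1prime", "exon1", "whole_gene_deletion"))
  expect_identical(out$effect, c("intronic", "missense", "copy_deletion"))
})
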