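# builders shared across test files

hb_case <- function(id = "S1", ...) {
  case_record(id, vhl_hgvs_c = "c.345C>A", vhl_classification = "VUS",
              personal_tumors = tumor_record("cns_hemangioblastoma"),
              age_years = 50, ...)
}

passing_snv <- function(source = "rcc", hgvs = "c.506_509delinsCG") {
  somatic_alteration("snv", hgvs_c = hgvs, vaf_percent = 30,
                     coverage = 200, unique_reads = 20,
                     population_af_percent = 0, tumor_source = source)
}

copy_loss <- function(source = "rcc", type = "one_copy_deletion") {
  somatic_alteration(type, log2_ratio = -0.9, tumor_source = source)
}

# independent brute-force oracle for somatic allelic status: literal hit
# weights per alteration kind, no shared code with the implementation
oracle_allelic <- function(kinds) {
  weights <- c(missense_snv = 1, null_snv = 1, one_copy_deletion = 1,
               two_copy_deletion = 2, amplification = 0, sv = NA)
  hits <- weights[kinds]
  if (length(kinds) == 0) return("no_inactivation")
  if (all(is.na(hits))) return("uninformative")
  total <- sum(hits, na.rm = TRUE)
  if (total == 0) "no_inactivation"
  else if (total == 1) "monoallelic_second_hit_candidate"
  else "biallelic_loh"
}

kind_to_alteration <- function(kind, source = "rcc") {
  switch(kind,
    missense_snv = passing_snv(source, "c.292T>C"),
    null_snv = passing_snv(source, "c.341-1G>A"),
    one_copy_deletion = copy_loss(source),
    two_copy_deletion = copy_loss(source, "two_copy_deletion"),
    amplification = somatic_alteration("amplification", log2_ratio = 0.6,
                                       tumor_source = source),
    sv = somatic_alteration("sv", tumor_source = source))
}

# all multisets of size <= n from a set of kinds
all_multisets <- function(kinds, n) {
  out <- list(character(0))
  for (size in seq_len(n)) {
    idx <- utils::combn(length(kinds) + size - 1, size, simplify = FALSE)
    sets <- unique(lapply(idx, function(ix) {
      sort(kinds[ix - seq_len(size) + 1])
    }))
    out <- c(out, sets)
  }
  out
}
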