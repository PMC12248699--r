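Package: vhlvef
Title: Integrated Germline and Somatic Evidence Framework for VHL Variant
    Actionability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based assessment of the clinical actionability of germline
    VHL variants from integrated evidence: germline genetics (zygosity,
    reported classification, differential-gene findings), clinical genetics
    (personal VHL tumors and features, family history), tumor-derived data,
    and somatic VHL alterations (second hit versus biallelic loss of
    heterozygosity).  Each case is encoded through a declarative scenario
    table into one of 17 codes across four actionability categories
    (Positive, Neutral, Negative, NOS).  Includes minimal HGVS cDNA parsing
    and exon/intron region mapping for VHL (including the cryptic exon E1'),
    somatic QC filters and log2 copy-number calls, per-variant recurrence and
    unique evidence-pattern quantification, de-identified portal-style
    variant export, and a deterministic synthetic-cohort generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
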