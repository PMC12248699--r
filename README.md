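# vhlvef

Integrated germline + somatic evidence assessment of **VHL** variant
actionability.

Deciding whether a germline *VHL* variant supports clinical action for
Von Hippel–Lindau syndrome requires more than the variant's reported
classification: the common component tumors (clear cell RCC above all)
are usually sporadic, several differential syndromes (*SDHx*, *FH*,
*FLCN*, *MET*, *BAP1*, *TMEM127*, *MAX*, *RET*, *NF1*) produce
overlapping tumors, *VHL* is also the gene of the recessive
erythrocytosis disorder ECYT2, and penetrance is age-related. `vhlvef`
is for clinical-genetics and variant-curation teams who want this
integration to be explicit, declarative, and testable.

## The model

Each case is reduced to a discrete evidence vector

> *T* = VHL component tumor count (per laterality, SDH-deficient
> paraganglioma excluded), *R* = RCC count within *T*, feature and
> non-VHL-tumor flags, *F* = family history of a VHL diagnosis in a
> first/second-degree relative, *S* = somatic *VHL* allelic status of
> the tumor profile, and an age band (young < 30 y),

after an eligibility gate (heterozygous germline *VHL* variant, no
P/LP differential-gene finding, evaluated in genetics). A declarative
scenario table — shipped as YAML and proven **total and disjoint** over
the whole discretized vector space at load time — maps the vector to
one of 17 codes in four categories:

| prefix | category | meaning |
|---|---|---|
| I-I…I-IV | Positive | all evidence aligns conservatively with VHL syndrome |
| II-I…II-VII | Neutral | strong but insufficient evidence |
| III-I…III-III | Negative | the pattern does not support VHL syndrome |
| IV-I…IV-III | NOS | a key piece of evidence is absent |

Somatic status follows the two-hit model: one QC-passing inactivating
event is a second-hit candidate (supports a constitutional tumor), two
or more (SNV + copy deletion, two SNVs, or a two-copy deletion alone)
are biallelic LOH, the signature of a sporadic tumor. Copy calls use
inclusive log2 thresholds (≥ 0.43 amplification, ≤ −0.32 loss); SNV QC
uses 50× coverage, 10 % VAF, 5 unique reads, 0.1 % population AF with a
COSMIC ≥ 2 rescue.

The package also provides minimal HGVS cDNA parsing with exon/intron
region mapping for *VHL* (including the deep-intron-1 cryptic exon
E1′), per-variant recurrence and unique evidence-pattern
quantification, de-identified portal-style JSON/TSV export, and a
deterministic scenario-first synthetic-cohort generator. See
`vignettes/vhl-evidence-framework.Rmd` for the full model description.

## Worked example

```r
library(vhlvef)
library(dplyr)

enc <- encode_cases(vef_fixture("patients_21_23"))
tidy(enc) |> select(subject_id, vhl_hgvs_c, age_years, vef_code, vef_category)
#> # A tibble: 3 × 5
#>   subject_id vhl_hgvs_c age_years vef_code vef_category
#>   <chr>      <chr>          <int> <chr>    <chr>
#> 1 P21        c.208G>A          16 II-VI    Neutral
#> 2 P22        c.345C>A          NA IV-II    NOS
#> 3 P23        c.532C>G          NA IV-II    NOS
```

The 16-year-old carrier with no personal findings but a first-degree
relative diagnosed with VHL syndrome gets II-VI: the absent phenotype
may be age-related, so the proband's age must be considered. The two
single-tumor cases without family history or somatic data get IV-II:
the evidence combination is insufficient for a complete assessment.

Aggregating a seven-carrier cohort of the deep-intronic variant
c.340+578C>T into a portal record:

```r
portal <- encode_cases(vef_fixture("portal_c340+578"))
unique_patterns(portal, "c.340+578C>T")$patterns
#> # A tibble: 2 × 4
#>   pattern                                  vef_code vef_category count
#>   <chr>                                    <chr>    <chr>        <int>
#> 1 T=0|R=0|feature=0|non_vhl_tumor=0|famil… III-III  Negative         4
#> 2 T=0|R=0|feature=0|non_vhl_tumor=1|famil… III-II   Negative         3

map_region("c.340+578C>T")
#> [1] "intron1_E1prime"
```

Recurrence 7, two distinct de-identified evidence patterns (four
carriers with no tumors, three with only non-VHL tumors), all
Negative — and the variant maps to the cryptic exon E1′, consistent
with an erythrocytosis rather than VHL-syndrome association.

A command-line wrapper is available for batch use:

```sh
exec/vhlvef encode --input cases.tsv --output coded.tsv --report report.json
exec/vhlvef simulate --n 100 --seed 7 --output cases.tsv --truth truth.tsv
exec/vhlvef portal-export --input cases.tsv --out portal.json
```

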