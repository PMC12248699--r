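---
title: "An integrated evidence framework for germline VHL variant actionability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated evidence framework for germline VHL variant actionability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhlvef)
library(dplyr)
```

## The problem

Von Hippel–Lindau (VHL) syndrome is an autosomal dominant cancer
syndrome caused by heterozygous germline loss-of-function variants in
the *VHL* tumor suppressor. Deciding whether a given germline *VHL*
variant is clinically actionable is hard because every line of evidence
is individually confounded:

* most VHL component tumors (clear cell RCC above all) are far more
  common as *sporadic* tumors driven by biallelic somatic *VHL* loss;
* several differential syndromes (*SDHx*, *FH*/HLRCC, *FLCN*/BHD,
  *MET*, *BAP1*, *TMEM127*, *MAX*, *RET*, *NF1*) produce overlapping
  tumors;
* *VHL* is also the gene of the recessive allelic disorder familial
  erythrocytosis type 2 (ECYT2), whose heterozygous carriers are not at
  VHL-syndrome risk; and
* penetrance is age-related, so an unaffected young carrier is not
  evidence against the variant.

This package encodes each case's *integrated* evidence — germline
variant and zygosity, differential-gene findings, personal tumors and
features, family history, and somatic *VHL* data — through a
declarative scenario table into one of 17 codes in four actionability
categories: **Positive** (I-I…I-IV, all evidence aligns conservatively
with VHL syndrome), **Neutral** (II-I…II-VII, strong but insufficient),
**Negative** (III-I…III-III, the pattern does not support VHL
syndrome), and **NOS** (IV-I…IV-III, a key piece of evidence is
absent).

## The evidence vector

`derive_vector()` reduces a validated case to the discrete quantities
the rules reason over:

| field | meaning |
|---|---|
| `eligible`, `gate_reason` | result of the eligibility gate |
| `n_vhl_tumors` (T) | component tumors, counted per laterality; SDH-deficient paragangliomas excluded |
| `n_rcc` (R) | RCC count within T |
| `has_vhl_feature` | kidney/pancreatic/epididymal-broad-ligament cysts |
| `has_non_vhl_tumor` | any non-component tumor |
| `family_history` (F) | positive only for a first/second-degree relative *diagnosed with VHL syndrome* |
| `somatic_available`, `somatic_status` (S) | allelic status of the component-tumor somatic profile |
| `age_band` | young (< 30 y by default), adult, unknown |

The gate admits only monoallelic (heterozygous) germline *VHL* variants
in patients evaluated in a genetics clinic with no P/LP finding in the
13-gene differential panel. Bi-allelic presentations are excluded
because the contribution of each allele cannot be assessed separately;
differential-positive cases are excluded because the tumors may be
explained by the other syndrome.

Somatic status comes from `allelic_status()` after QC filtering: one
inactivating event is a *second-hit candidate* (supporting a
constitutional tumor in a germline carrier, per the two-hit model), two
or more inactivating hits (SNV + copy deletion, two SNVs, or a two-copy
deletion alone) are *biallelic LOH*, the signature of a sporadic tumor.
Amplifications never count as inactivating (VHL disease is loss of
function), synonymous and deep-intronic SNVs do not count, and SV-only
profiles are uninformative.

## The scenario table is data

The 17 scenarios ship as a YAML file
(`system.file("extdata", "vef_vhl_scenarios.yaml", package = "vhlvef")`)
rather than code. The loader proves three properties before any
classification: all 17 codes are present; each code's roman prefix
matches its category; and the rules are **total and pairwise disjoint**
over the exhaustively enumerated discretized evidence-vector space
(1,804 vectors — tumor counts truncated at 3 because every rule
condition saturates at 2). Priorities exist only as a safety net; the
disjointness proof makes them irrelevant.

The published constraints anchor the table: the somatic-gated codes are
exactly {I-II, I-III, II-I, II-II, II-III, III-I}; the multi-tumor
family spans {I-I, I-II, I-IV, II-I, II-IV, II-VII}; the age-related
codes are {II-V, II-VI, II-VII}; II-VI and IV-II reproduce the three
published patient vignettes; III-II/III-III are the non-VHL-tumor /
no-tumor Negative codes. Where the published material does not pin a
cell of the space, this package fixes it by design and records the
choice here:

* **II-IV / II-VII** accept any presentation with ≥ 2 RCC (not only
  all-RCC presentations), so that mixed multi-tumor cases with ≥ 2 RCC
  and no qualifying family history remain classifiable.
* **IV-II** additionally covers (a) multi-tumor cases with exactly one
  RCC and *no* somatic data — somatic evidence is required there and
  absent — and (b) isolated VHL-related features in adults.
* **II-VI** also covers single-tumor cases with a qualifying family
  history whose somatic data fail to show a single second hit.
* **II-V** covers any young patient (T ≤ 1) with a negative family
  history who is not otherwise informative: an absent phenotype before
  the typical ages of onset is not evidence.
* **F = unknown** with otherwise insufficient evidence routes to the
  NOS family (IV-III), never coerced to negative.
* Features alone never satisfy a Positive scenario.
* A family history at third degree or further does not meet the
  criterion and is treated as negative.

The file's provenance block marks the table as a reconstruction; an
authoritative table can replace it without code changes.

A documented textual tension in the source material: the two
single-tumor patient vignettes are described as "Neutral variants" yet
carry code IV-II; this package follows the code→category mapping
(IV-* is NOS), which their "insufficient for a complete assessment"
description matches.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `age_young_threshold` | 30 y | mean ages at diagnosis of component tumors span ~22–39 y |
| `het_vaf_band` | 40–60 % | only the out-of-band medians (27 % / 68 %) are published, not the band; 40–60 is the conventional heterozygous window |
| `min_coverage` / `min_vaf_percent` | 50× / 10 % | the panel assay's validated limit of detection |
| `min_unique_reads` | 5 | read-support filter |
| `max_population_af_percent` | 0.1 % | ESP/gnomAD exclusion; COSMIC count ≥ 2 rescues |
| `amp_log2_min` / `loss_log2_max` | 0.43 / −0.32 | copy-call thresholds, both **inclusive** ("or higher"/"or lower") |

Missing QC metrics pass the filter by default because retrospective
records often lack fields; `somatic_qc_config(strict = TRUE)` rejects
on missing metrics instead.

## Degenerate inputs and tie-breaks

Unknown zygosity is gated out (monoallelic status unconfirmed). Missing
age maps to `age_band = "unknown"`, which the table treats like adult
wherever the distinction matters — only "young" relaxes
interpretation. A positive family history without a recorded degree is
taken at face value. Somatic alterations whose `tumor_source` is not a
VHL component tumor are excluded from the allelic status; if only such
records remain the status is uninformative. Invalid rows are carried
through an encoding as the fallback code IV-I with the validation
message in `comment` (strict mode aborts), because retrospective
cohorts contain incomplete records by design.

## The synthetic generator

`generate_cohort()` is scenario-first: each case draws its target code
from the requested mix by exact largest-remainder apportionment, is
constructed to satisfy that scenario's predicate, and is then decorated
with a variant from the recurrent clinical *VHL* variant pool, a
reported classification (VUS-dominated by default, mirroring clinical
cohorts), sex (74 % female by default) and an age drawn uniformly in
the band the scenario requires (10–29 y young, 30–80 y adult). The same
spec and seed produce byte-identical output, and encoding a generated
cohort recovers the mix exactly — by construction, not sampling — which
is what makes the engine's recovery test an exact check.

What the generator does **not** emulate: realistic population allele
frequencies, VAF noise and assay artifacts, correlated tumor spectra,
or the marginal composition of any real cohort. Passing tests therefore
demonstrate the correctness of the encoding machinery, not the clinical
performance of the framework on real patients; cohort-level percentages
from real data cannot be reproduced from synthetic cases and are not
asserted anywhere.

## Worked examples

```{r}
enc <- encode_cases(vef_fixture("patients_21_23"))
tidy(enc) |> select(subject_id, vhl_hgvs_c, vef_code, vef_category)
```

```{r}
portal <- encode_cases(vef_fixture("portal_c340+578"))
unique_patterns(portal, "c.340+578C>T")$patterns
```

The seven-carrier deep-intronic variant sits in the cryptic exon E1′:

```{r}
map_region("c.340+578C>T")
```

E1′ has no published coordinates; the default transcript map declares
the window as intron-1 offsets +400…+800, chosen to contain every named
E1′ variant, and records it in the map file so that output is traceable
to the assumption. Effect classification is structural only — the
synonymous c.429C>T keeps class `synonymous` despite its reported
functional splice effect, since functional reinterpretation is out of
scope. Nonsense calls that cannot be derived from cDNA syntax use a
small curated table of literature-reported protein consequences.

## Test problem sizes

The suite enumerates all 1,804 discretized evidence vectors for the
totality/disjointness proof, all somatic multisets of size ≤ 3 against
a brute-force oracle, random cohorts of ≤ 100 cases against a pairwise
group-by oracle for the pattern quantifier, and a 1,000-case synthetic
cohort for exact scenario-mix recovery.

## Known limitations

Copy-neutral LOH and promoter hypermethylation are invisible to this
data model, so some truly biallelic tumors will be called monoallelic
or uninformative; allelic status rests on genetic evidence only.
Mosaicism and low-VAF germline variants are out of scope. The scenario
table is a validated reconstruction, not the authoritative appendix.
HGVS support covers the clinical cDNA dialect, not the full grammar,
and genomic coordinates are not supported.
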