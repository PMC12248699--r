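# Minimal HGVS cDNA parsing for VHL and region/effect assignment.
# Supports the c.-prefixed dialect used in clinical reports: substitutions
# (c.292T>C), splice/intronic offset forms (c.341-1G>A, c.340+578C>T),
# del/dup/ins/delins with optional ranges (c.506_509delinsCG,
# c.340+694_340+711dup). Genomic (g.) coordinates, full HGVS grammar and
# protein-level parsing beyond simple consequence strings are out of scope.

cdna_token <- "(\\*?\\-?\\d+)([+-]\\d+)?"

strip_gene_prefix <- function(x) {
  x <- stringr::str_replace_all(x, "\\s+", "")
  stringr::str_remove(x, stringr::regex("^VHL:", ignore_case = TRUE))
}

#' Parse an HGVS cDNA description
#'
#' Parses the cDNA dialect used in clinical VHL reports into a structured
#' position: CDS base, optional intronic offset, optional range end, and
#' the change kind (substitution, del, dup, ins, delins).
#'
#' @param hgvs_c A `c.`-prefixed string, optionally with a `VHL:` gene
#'   prefix; whitespace is ignored.
#' @return A list with elements `kind`, `start`, `start_offset`, `end`,
#'   `end_offset`, `ref`, `alt` (unused slots are `NA`).
#' @examples
#' parse_cdna("c.340+578C>T")
#' parse_cdna("c.506_509delinsCG")
#' @export
parse_cdna <- function(hgvs_c) {
  stopifnot(is.character(hgvs_c), length(hgvs_c) == 1, !is.na(hgvs_c))
  x <- strip_gene_prefix(hgvs_c)
  if (stringr::str_starts(x, "p\\.")) {
    stop("bad_hgvs: protein-level description '", hgvs_c,
         "' (cDNA c. form required)")
  }
  if (!stringr::str_starts(x, "c\\.")) {
    stop("bad_hgvs: '", hgvs_c, "' does not start with 'c.'")
  }
  body <- stringr::str_sub(x, 3)

  pos_part <- function(m) {
    start <- suppressWarnings(as.integer(stringr::str_remove(m[1], "\\*")))
    if (stringr::str_detect(m[1], "^\\*")) start <- NA_integer_  # 3'UTR
    offset <- if (is.na(m[2]) || !nzchar(m[2])) 0L
              else as.integer(m[2])
    list(start = start, offset = offset, utr3 = stringr::str_detect(
      m[1], "^\\*"))
  }

  # substitution: <pos>R>A
  m <- stringr::str_match(
    body, paste0("^", cdna_token, "([ACGTacgt])>([ACGTacgt])$"))
  if (!is.na(m[1, 1])) {
    p <- pos_part(m[1, 2:3])
    return(list(kind = "substitution", start = p$start,
                start_offset = p$offset, end = p$start,
                end_offset = p$offset, ref = toupper(m[1, 4]),
                alt = toupper(m[1, 5]), utr3 = p$utr3))
  }

  # del / dup / ins / delins with optional range
  m <- stringr::str_match(
    body, paste0("^", cdna_token, "(?:_", cdna_token, ")?",
                 "(delins|del|dup|ins)([ACGTacgt]*)$"))
  if (!is.na(m[1, 1])) {
    p1 <- pos_part(m[1, 2:3])
    has_end <- !is.na(m[1, 4])
    p2 <- if (has_end) pos_part(m[1, 4:5]) else p1
    return(list(kind = m[1, 6], start = p1$start,
                start_offset = p1$offset, end = p2$start,
                end_offset = p2$offset, ref = NA_character_,
                alt = if (nzchar(m[1, 7])) toupper(m[1, 7])
                      else NA_character_,
                utr3 = p1$utr3 || p2$utr3))
  }
  stop("bad_hgvs: cannot parse '", hgvs_c, "'")
}

is_parseable_cdna <- function(hgvs_c) {
  !inherits(try(parse_cdna(hgvs_c), silent = TRUE), "try-error")
}

#' Transcript maps
#'
#' `default_transcript_map()` loads the transcript map shipped with the
#' package (canonical VHL coding exon bounds c.1-340, c.341-463,
#' c.464-642 and the E1' intron-1 offset window 400-800);
#' `load_transcript_map()` reads an alternative map from a YAML file with
#' fields `transcript_id`, `cds_exon_bounds`, `e1prime_window`,
#' `utr_allowance`.
#'
#' @param path Path to a YAML transcript map.
#' @return A list of class `transcript_map`.
#' @export
load_transcript_map <- function(path) {
  raw <- yaml::read_yaml(path)
  bounds <- do.call(rbind, lapply(raw$cds_exon_bounds, as.integer))
  stopifnot(ncol(bounds) == 2, nrow(bounds) >= 1,
            all(bounds[, 1] <= bounds[, 2]))
  if (nrow(bounds) > 1) {
    stopifnot(all(bounds[-1, 1] == bounds[-nrow(bounds), 2] + 1L))
  }
  win <- as.integer(raw$e1prime_window)
  stopifnot(length(win) == 2, win[1] > 0, win[1] <= win[2])
  structure(
    list(transcript_id = raw$transcript_id,
         cds_exon_bounds = bounds,
         e1prime_window = win,
         utr_allowance = as.integer(raw$utr_allowance %||% 0L)),
    class = "transcript_map")
}

#' @rdname load_transcript_map
#' @export
default_transcript_map <- function() {
  load_transcript_map(system.file("extdata", "vhl_transcript.yaml",
                                  package = "vhlvef", mustWork = TRUE))
}

gene_regions <- function() {
  c("exon1", "intron1", "intron1_E1prime", "exon2", "intron2", "exon3",
    "multi_exon_deletion", "whole_gene_deletion", "other")
}

#' Map a parsed cDNA position to a gene region
#'
#' Assigns each parseable position to exactly one region: a coding exon,
#' an intron (with intron-1 positions inside the E1' window reported as
#' `intron1_E1prime`), or `other` for UTR positions beyond the map's
#' allowance. Whole-gene and multi-exon deletions are mapped with
#' [deletion_region()] from their deleted-exon set.
#'
#' @param parsed Output of [parse_cdna()] (a string is parsed first).
#' @param tmap A transcript map, default [default_transcript_map()].
#' @return A single region name (see [gene_regions()]).
#' @examples
#' map_region("c.340+578C>T")  # intron1_E1prime
#' @export
map_region <- function(parsed, tmap = default_transcript_map()) {
  if (is.character(parsed)) parsed <- parse_cdna(parsed)
  bounds <- tmap$cds_exon_bounds
  cds_end <- bounds[nrow(bounds), 2]
  pos <- parsed$start
  off <- parsed$start_offset
  if (isTRUE(parsed$utr3) || is.na(pos)) return("other")
  if (pos < 1 || pos > cds_end + tmap$utr_allowance) return("other")
  if (off == 0) {
    exon <- which(pos >= bounds[, 1] & pos <= bounds[, 2])
    return(paste0("exon", exon[1]))
  }
  # intronic: a positive offset hangs off the exon ending at `pos`, a
  # negative offset off the exon starting at `pos`
  exon_of <- which(pos >= bounds[, 1] & pos <= bounds[, 2])[1]
  intron <- if (off > 0) exon_of else exon_of - 1L
  if (is.na(intron) || intron < 1 || intron >= nrow(bounds) + 1) {
    return("other")
  }
  if (intron == 1 && off >= tmap$e1prime_window[1] &&
      off <= tmap$e1prime_window[2]) {
    return("intron1_E1prime")
  }
  if (intron > nrow(bounds) - 1) return("other")
  paste0("intron", intron)
}

#' @rdname map_region
#' @param deleted_exons Integer vector of deleted exons (subset of the
#'   map's exons).
#' @export
deletion_region <- function(deleted_exons,
                            tmap = default_transcript_map()) {
  deleted_exons <- sort(unique(as.integer(deleted_exons)))
  if (length(deleted_exons) == 0) return("other")
  if (setequal(deleted_exons, seq_len(nrow(tmap$cds_exon_bounds)))) {
    return("whole_gene_deletion")
  }
  "multi_exon_deletion"
}

effect_classes <- function() {
  c("missense", "null", "synonymous", "intronic", "copy_deletion", "other")
}

protein_annotation_table <- function() {
  readr::read_tsv(system.file("extdata", "vhl_protein_annotations.tsv",
                              package = "vhlvef", mustWork = TRUE),
                  col_types = "cc")
}

classify_from_protein <- function(hgvs_p) {
  p <- stringr::str_replace_all(hgvs_p, "[\\s()]", "")
  p <- stringr::str_remove(p, stringr::regex("^VHL:",
                                             ignore_case = TRUE))
  p <- stringr::str_remove(p, "^p\\.")
  if (stringr::str_detect(p, "fs|Ter$|\\*$|^Met1\\?$")) return("null")
  if (stringr::str_detect(p, "=$")) return("synonymous")
  if (stringr::str_detect(p,
      "^[A-Z][a-z]{2}\\d+[A-Z][a-z]{2}$|^[A-Z]\\d+[A-Z]$")) {
    return("missense")
  }
  "other"
}

#' Classify the structural effect of a variant
#'
#' Classifies a variant as `missense`, `null` (nonsense, frameshift,
#' canonical +/-1/+/-2 splice, start-loss), `synonymous`, `intronic`
#' (offset beyond the canonical splice positions), `copy_deletion`, or
#' `other`. When `hgvs_p` is absent, a small curated table of
#' literature-reported protein consequences for named VHL variants is
#' consulted; an exonic substitution with no protein information defaults
#' to `missense`. The classification is structural only: a synonymous
#' variant with a reported functional splice effect still classifies
#' `synonymous`.
#'
#' @param hgvs_c cDNA description (may be `NA` for pure copy-number
#'   variants).
#' @param hgvs_p Optional protein description (e.g. `"p.Tyr98His"`,
#'   parentheses and whitespace ignored).
#' @param deleted_exons Optional deleted-exon set; non-empty returns
#'   `copy_deletion`.
#' @return One of [effect_classes()].
#' @examples
#' classify_effect("c.341-1G>A")          # null (canonical splice)
#' classify_effect("c.429C>T")            # synonymous (curated p.Asp143=)
#' classify_effect("c.292T>C", "p.(Tyr98His)")
#' @export
classify_effect <- function(hgvs_c = NA_character_, hgvs_p = NULL,
                            deleted_exons = integer(0)) {
  if (length(deleted_exons) > 0) return("copy_deletion")
  if (is.na(hgvs_c) && is.null(hgvs_p)) {
    stop("at least one of hgvs_c / hgvs_p is required")
  }
  class_p <- if (!is.null(hgvs_p) && !is.na(hgvs_p)) {
    classify_from_protein(hgvs_p)
  } else {
    key <- normalize_variant_key(hgvs_c)
    tab <- protein_annotation_table()
    hit <- match(key, normalize_variant_key(tab$hgvs_c))
    if (!is.na(hit)) classify_from_protein(tab$hgvs_p[hit]) else NA
  }
  if (is.na(hgvs_c)) return(class_p %||% "other")

  parsed <- parse_cdna(hgvs_c)
  off <- parsed$start_offset
  end_off <- parsed$end_offset
  class_c <- if (off != 0 || end_off != 0) {
    if (abs(off) <= 2 || abs(end_off) <= 2) "null" else "intronic"
  } else if (parsed$kind %in% c("del", "dup", "ins", "delins")) {
    span <- parsed$end - parsed$start + 1L
    changed <- switch(parsed$kind,
      del = -span,
      dup = span,
      ins = nchar(parsed$alt %||% ""),
      delins = nchar(parsed$alt %||% "") - span)
    if (changed %% 3 != 0) "null" else "other"
  } else if (parsed$kind == "substitution" && parsed$start <= 3) {
    "null"  # start-codon substitution
  } else {
    NA_character_
  }

  if (!is.na(class_c) && !is.na(class_p %||% NA) &&
      class_c != class_p && class_c %in% c("intronic") &&
      class_p %in% c("missense", "synonymous")) {
    stop("annotation_conflict: '", hgvs_c, "' is intronic but '",
         hgvs_p, "' describes a coding change")
  }
  if (!is.na(class_c)) return(class_c)
  if (!is.na(class_p %||% NA)) return(class_p)
  if (parsed$kind == "substitution") return("missense")
  "other"
}

#' Annotate a variant table with region and effect
#'
#' Appends `region` and `effect` columns to any tibble holding an HGVS
#' cDNA column (and optionally a `deleted_exons` list-column for germline
#' copy-number variants).
#'
#' @param df A tibble.
#' @param hgvs_col Name of the cDNA column.
#' @param tmap Transcript map.
#' @return `df` with `region` and `effect` columns added.
#' @export
annotate_variants <- function(df, hgvs_col = "vhl_hgvs_c",
                              tmap = default_transcript_map()) {
  del <- if ("deleted_exons" %in% names(df)) df$deleted_exons
         else rep(list(integer(0)), nrow(df))
  hg <- df[[hgvs_col]]
  ann <- purrr::map2(hg, del, function(h, d) {
    if (length(d) > 0) {
      list(region = deletion_region(d, tmap), effect = "copy_deletion")
    } else if (is.na(h) || !is_parseable_cdna(h)) {
      list(region = NA_character_, effect = NA_character_)
    } else {
      list(region = map_region(parse_cdna(h), tmap),
           effect = classify_effect(h))
    }
  })
  df$region <- purrr::map_chr(ann, "region")
  df$effect <- purrr::map_chr(ann, "effect")
  df
}
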