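#' Read a pileup count table
#'
#' A pileup table is a per-locus tally of read bases for one sample:
#' tab-separated with a header row and columns `sample_id`, `chrom`,
#' `pos` (1-based), `ref_base`, `depth`, `count_A`, `count_C`, `count_G`,
#' `count_T`. Counts are reads observed per base at that locus; each count
#' must not exceed `depth`, and the four counts may sum to less than `depth`
#' (reads with ambiguous calls).
#'
#' @param path Path to a pileup TSV. Lines starting with `#` are skipped.
#' @return A tibble with the columns above, `chrom` normalised to the
#'   `chr`-prefixed dialect. An empty data section yields an empty tibble
#'   with a warning.
#' @seealso [write_pileup()], [call_somatic()]
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) abort(sprintf("pileup not found: %s", path))
  x <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref_base = readr::col_character(),
      depth = readr::col_integer(),
      count_A = readr::col_integer(), count_C = readr::col_integer(),
      count_G = readr::col_integer(), count_T = readr::col_integer()
    )
  )
  needed <- c("sample_id", "chrom", "pos", "ref_base", "depth",
              "count_A", "count_C", "count_G", "count_T")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("pileup %s lacks column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    warn(sprintf("pileup %s has a header but no records", path))
    return(as_tibble(x))
  }
  x$chrom <- normalize_chrom(x$chrom)
  validate_pileup(x, path)
  as_tibble(x)
}

# Structural checks shared by the reader and the simulator output; `where`
# labels diagnostics. Row numbers are data rows (header excluded).
validate_pileup <- function(x, where = "pileup") {
  bad_base <- which(!x$ref_base %in% BASES)
  if (length(bad_base) > 0) {
    abort(sprintf("%s: unknown ref_base at data row(s) %s", where,
                  paste(head(bad_base, 5), collapse = ", ")))
  }
  counts <- as.matrix(x[c("count_A", "count_C", "count_G", "count_T")])
  if (any(counts < 0) || any(x$depth < 0)) {
    abort(sprintf("%s: negative counts or depth", where))
  }
  over <- which(apply(counts, 1, max) > x$depth)
  if (length(over) > 0) {
    abort(sprintf("%s: base count exceeds depth at data row(s) %s", where,
                  paste(head(over, 5), collapse = ", ")))
  }
  if (anyDuplicated(x[c("chrom", "pos")]) > 0) {
    abort(sprintf("%s: duplicated (chrom, pos) loci", where))
  }
  invisible(x)
}

#' Write a pileup count table
#'
#' @param pileup Pileup tibble (see [read_pileup()] for the schema).
#' @param path Output TSV path.
#' @return `path`, invisibly. Write then read is the identity on valid
#'   tables.
#' @export
write_pileup <- function(pileup, path) {
  check_pileup(pileup)
  readr::write_tsv(pileup, path, progress = FALSE)
  invisible(path)
}

#' Read / write a locus blacklist
#'
#' The blacklist flags loci known to produce recurrent artifactual variant
#' signal across samples ("systematic positives"); candidate variants at
#' these positions are flagged rather than accepted. Format: TSV with
#' columns `chrom`, `pos` (1-based).
#'
#' @param path Path to the blacklist TSV.
#' @return A tibble with unique `(chrom, pos)` rows, `chrom` normalised.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) abort(sprintf("blacklist not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(chrom = readr::col_character(),
                                               pos = readr::col_integer()))
  if (!all(c("chrom", "pos") %in% names(x))) {
    abort("blacklist needs columns chrom, pos")
  }
  x$chrom <- normalize_chrom(x$chrom)
  dplyr::distinct(as_tibble(x), .data$chrom, .data$pos)
}

#' @rdname read_blacklist
#' @param blacklist Blacklist tibble.
#' @export
write_blacklist <- function(blacklist, path) {
  readr::write_tsv(blacklist[c("chrom", "pos")], path, progress = FALSE)
  invisible(path)
}

MUTATION_EFFECTS <- c("NON_SYNONYMOUS", "STOP_GAINED", "SILENT", "SPLICE_SITE")

#' Read an annotated mutation table
#'
#' Loads a table of accepted point mutations, one row per mutation per
#' patient, with columns `gene`, `chrom`, `pos`, `ref_base`, `alt_base`,
#' `effect`, `cds_change`, `protein_change`, `sample_id`. The effect
#' vocabulary is closed: `NON_SYNONYMOUS`, `STOP_GAINED`, `SILENT`,
#' `SPLICE_SITE`. `cds_change` uses the single-uppercase codon dialect
#' (e.g. `"aTc/aCc"`: the capital letter marks the substituted position).
#' Chromosomes with or without a `chr` prefix are accepted and normalised
#' to the prefixed form.
#'
#' A 26-mutation table observed in a 37-patient head and neck squamous cell
#' carcinoma cohort ships with the package:
#' `system.file("extdata", "hnscc_mutations.tsv", package = "somaticpair")`.
#'
#' @param path Path to the TSV.
#' @return A tibble with the columns above.
#' @seealso [verify_mutation_table()], [summarize_mutations()]
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("mutation table not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(
                         gene = readr::col_character(),
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         ref_base = readr::col_character(),
                         alt_base = readr::col_character(),
                         effect = readr::col_character(),
                         cds_change = readr::col_character(),
                         protein_change = readr::col_character(),
                         sample_id = readr::col_character()))
  needed <- c("gene", "chrom", "pos", "ref_base", "alt_base", "effect",
              "cds_change", "protein_change", "sample_id")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("mutation table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!x$effect %in% MUTATION_EFFECTS)
  if (length(bad) > 0) {
    abort(sprintf("unknown effect label(s) %s at data row(s) %s",
                  paste(unique(x$effect[bad]), collapse = ", "),
                  paste(head(bad, 5), collapse = ", ")))
  }
  x$chrom <- normalize_chrom(x$chrom)
  as_tibble(x)
}

#' Write somatic calls as VCF
#'
#' Serialises a call table from [call_somatic()] to VCFv4.2. Accepted calls
#' get `FILTER` `PASS`; filtered candidates carry their flags as a
#' semicolon-joined, alphabetically ordered `FILTER` value drawn from
#' `low_coverage`, `low_vaf`, `germline`, `systematic`, `blacklist`.
#' `INFO` carries `TVAF`, `NVAF`, `SCOREDIFF` and, when present, `GENE` and
#' `EFFECT`. Records are sorted by `(chrom, pos)`; unsorted input is sorted,
#' never rejected.
#'
#' @param calls A `somatic_calls` tibble (or any tibble with the same
#'   columns).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticpair",
    "##FILTER=<ID=low_coverage,Description=\"Locus failed the per-sample coverage gate (depth must exceed both the minimum read count and the median-coverage fraction)\">",
    "##FILTER=<ID=low_vaf,Description=\"Tumor variant allele fraction below the mutation read frequency threshold\">",
    "##FILTER=<ID=germline,Description=\"Matched normal shows variant reads above the germline threshold (or has zero depth)\">",
    "##FILTER=<ID=systematic,Description=\"Variant score difference within the background percentile of pairwise differences\">",
    "##FILTER=<ID=blacklist,Description=\"Locus on the systematic-positive blacklist\">",
    "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Tumor variant allele fraction\">",
    "##INFO=<ID=NVAF,Number=1,Type=Float,Description=\"Normal variant allele fraction\">",
    "##INFO=<ID=SCOREDIFF,Number=1,Type=Float,Description=\"Tumor minus normal Phred-scaled variant score\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (any(is.na(calls$ref_base)) || any(is.na(calls$alt_base))) {
    abort("calls with missing ref/alt cannot be written to VCF")
  }
  calls <- dplyr::arrange(calls, .data$chrom, .data$pos)
  filter_col <- vapply(calls$filters, function(f) {
    if (is.na(f) || !nzchar(f)) "PASS"
    else paste(sort(strsplit(f, ";", fixed = TRUE)[[1]]), collapse = ";")
  }, character(1))
  info <- sprintf("TVAF=%.6g;NVAF=%.6g;SCOREDIFF=%.6g",
                  calls$tumor_vaf, calls$normal_vaf, calls$score_diff)
  if ("gene" %in% names(calls)) {
    info <- ifelse(is.na(calls$gene), info,
                   paste0(info, ";GENE=", calls$gene))
  }
  if ("effect" %in% names(calls)) {
    info <- ifelse(is.na(calls$effect), info,
                   paste0(info, ";EFFECT=", calls$effect))
  }
  records <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                     calls$chrom, calls$pos, calls$ref_base, calls$alt_base,
                     filter_col, info)
  writeLines(c(header, records), path)
  invisible(path)
}
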