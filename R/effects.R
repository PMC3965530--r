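#' Parse a CDS change string
#'
#' CDS changes use the compact codon dialect `"aTc/aCc"`: reference and
#' alternate codon separated by `/`, written in lowercase except for the
#' single substituted position, which is uppercase in both codons at the
#' same index. Parsing rejects codons that are not length 3, that carry
#' zero or more than one uppercase letter, whose uppercase positions
#' disagree, or that are identical.
#'
#' @param text Character vector of CDS change strings.
#' @param codon_number Optional integer vector of protein positions carried
#'   through to the result.
#' @return A tibble with `ref_codon`, `alt_codon` (uppercased),
#'   `changed_index` (0-based: 0, 1 or 2) and `codon_number`.
#' @examples
#' parse_cds_change("aTc/aCc")  # ATC -> ACC at index 1
#' parse_cds_change("Gag/Tag")  # GAG -> TAG at index 0
#' @export
parse_cds_change <- function(text, codon_number = NA_integer_) {
  codon_number <- rep_len(as.integer(codon_number), length(text))
  parts <- stringr::str_split_fixed(text, stringr::fixed("/"), 2)
  ref <- parts[, 1]
  alt <- parts[, 2]
  bad <- function(msg, which) {
    abort(sprintf("invalid CDS change %s: %s",
                  paste(sQuote(text[which]), collapse = ", "), msg))
  }
  ok_codon <- grepl("^[ACGTacgt]{3}$", ref) & grepl("^[ACGTacgt]{3}$", alt)
  if (any(!ok_codon)) bad("codons must be 3 letters over ACGT", !ok_codon)

  upper_at <- function(x) {
    m <- stringr::str_locate_all(x, "[ACGT]")
    n_up <- vapply(m, nrow, integer(1))
    idx <- vapply(m, function(p) if (nrow(p) == 1) p[1, 1] else NA_real_,
                  numeric(1))
    list(n = n_up, idx = idx)
  }
  ur <- upper_at(ref)
  ua <- upper_at(alt)
  one_up <- ur$n == 1 & ua$n == 1
  if (any(!one_up)) bad("exactly one uppercase letter per codon", !one_up)
  same_idx <- ur$idx == ua$idx
  if (any(!same_idx)) bad("uppercase positions disagree", !same_idx)

  ref_u <- toupper(ref)
  alt_u <- toupper(alt)
  if (any(ref_u == alt_u)) bad("codons are identical", ref_u == alt_u)
  # the marked position must be the (only) differing position
  diff_count <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, ref_u, alt_u)
  marked_differs <- substr(ref_u, ur$idx, ur$idx) != substr(alt_u, ua$idx, ua$idx)
  if (any(diff_count != 1 | !marked_differs)) {
    bad("codons must differ exactly at the marked position",
        diff_count != 1 | !marked_differs)
  }

  tibble(ref_codon = ref_u, alt_codon = alt_u,
         changed_index = as.integer(ur$idx - 1),
         codon_number = codon_number)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[toupper(codon)]
  if (any(is.na(aa))) abort("codon with non-ACGT character")
  unname(aa)
}

#' Classify the effect of a single-codon substitution
#'
#' Translates both codons with the standard genetic code. A substitution is
#' `STOP_GAINED` (nonsense) when the alternate codon is a stop and the
#' reference is not, `SILENT` when both encode the same amino acid, and
#' `NON_SYNONYMOUS` (missense) otherwise. Stop-loss (reference is a stop)
#' is classified `NON_SYNONYMOUS` with a warning. `SPLICE_SITE` is part of
#' the effect vocabulary but is a property of the locus, not of codon
#' content, and is never inferred here.
#'
#' @param ref_codon,alt_codon Character vectors of 3-letter DNA codons
#'   (case-insensitive).
#' @return Character vector of effect classes.
#' @examples
#' classify_effect("GAG", "TAG")  # STOP_GAINED (E -> *)
#' classify_effect("ATC", "ACC")  # NON_SYNONYMOUS (I -> T)
#' classify_effect("AAA", "AAG")  # SILENT (K -> K)
#' @export
classify_effect <- function(ref_codon, alt_codon) {
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (any(ref_aa == "*" & alt_aa != "*")) {
    warn("stop-loss substitution classified NON_SYNONYMOUS")
  }
  dplyr::case_when(
    alt_aa == "*" & ref_aa != "*" ~ "STOP_GAINED",
    ref_aa == alt_aa ~ "SILENT",
    TRUE ~ "NON_SYNONYMOUS"
  )
}

#' Protein change notation
#'
#' Renders a codon substitution as `p.<refAA><position><altAA>` with stop
#' codons written `*` (e.g. `p.R56*`).
#'
#' @param ref_codon,alt_codon 3-letter DNA codons.
#' @param codon_number Protein position (1-based).
#' @return Character vector like `"p.I96T"`.
#' @examples
#' protein_change("ATC", "ACC", 96)  # "p.I96T"
#' protein_change("CGA", "TGA", 56)  # "p.R56*"
#' @export
protein_change <- function(ref_codon, alt_codon, codon_number) {
  sprintf("p.%s%d%s", translate_codon(ref_codon), as.integer(codon_number),
          translate_codon(alt_codon))
}

#' Re-annotate a mutation table from its CDS changes
#'
#' Recomputes `effect` and `protein_change` for every row of a mutation
#' table from its `cds_change` string (taking the protein position from the
#' printed `protein_change`), returning the table with `effect_recomputed`
#' and `protein_change_recomputed` columns appended.
#'
#' @param table Mutation table ([read_mutation_table()]).
#' @return The input tibble with the two recomputed columns.
#' @export
annotate_effects <- function(table) {
  cn <- as.integer(stringr::str_match(table$protein_change,
                                      "^p\\.[A-Z*](\\d+)[A-Z*]$")[, 2])
  parsed <- parse_cds_change(table$cds_change, cn)
  table$effect_recomputed <- classify_effect(parsed$ref_codon,
                                             parsed$alt_codon)
  table$protein_change_recomputed <- protein_change(
    parsed$ref_codon, parsed$alt_codon, parsed$codon_number)
  table
}

#' Verify a mutation table's printed annotations
#'
#' For each row, re-parses the CDS change, re-classifies the effect and
#' re-derives the protein change, then compares against the printed values.
#' Unparseable rows are reported, not raised.
#'
#' @param table Mutation table ([read_mutation_table()]).
#' @return A tibble of class `mutation_check` with one row per discrepancy
#'   (`row`, `field` in `effect`/`protein_change`/`cds_change`, `printed`,
#'   `recomputed`); zero rows means every annotation is internally
#'   consistent. The attribute `n_checked` records the number of rows
#'   examined.
#' @examples
#' tbl <- read_mutation_table(system.file("extdata", "hnscc_mutations.tsv",
#'                                        package = "somaticpair"))
#' verify_mutation_table(tbl)  # zero rows: table is self-consistent
#' @export
verify_mutation_table <- function(table) {
  report <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    rec <- table[i, ]
    cn <- as.integer(stringr::str_match(rec$protein_change,
                                        "^p\\.[A-Z*](\\d+)[A-Z*]$")[, 2])
    parsed <- tryCatch(parse_cds_change(rec$cds_change, cn),
                       error = function(e) NULL)
    if (is.null(parsed)) {
      return(tibble(row = i, field = "cds_change",
                    printed = rec$cds_change,
                    recomputed = NA_character_))
    }
    # splice-site annotations are locus properties; codon content cannot
    # confirm or refute them
    if (identical(rec$effect, "SPLICE_SITE")) return(NULL)
    eff <- classify_effect(parsed$ref_codon, parsed$alt_codon)
    prot <- if (!is.na(parsed$codon_number)) {
      protein_change(parsed$ref_codon, parsed$alt_codon, parsed$codon_number)
    } else NA_character_
    printed_eff <- rec$effect
    printed_prot <- rec$protein_change
    out <- NULL
    if (!identical(eff, printed_eff)) {
      out <- dplyr::bind_rows(out, tibble(
        row = i, field = "effect", printed = printed_eff, recomputed = eff))
    }
    if (!is.na(prot) && !identical(prot, printed_prot)) {
      out <- dplyr::bind_rows(out, tibble(
        row = i, field = "protein_change", printed = printed_prot,
        recomputed = prot))
    }
    out
  })
  if (nrow(report) == 0) {
    report <- tibble(row = integer(), field = character(),
                     printed = character(), recomputed = character())
  }
  attr(report, "n_checked") <- nrow(table)
  class(report) <- c("mutation_check", class(report))
  report
}
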