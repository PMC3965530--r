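#' Read a targeted gene panel from BED
#'
#' Parses a BED file (0-based, half-open intervals) describing the loci of a
#' targeted cancer gene panel. The fourth (name) column carries the gene
#' symbol, optionally suffixed with the sequencing design for that gene as
#' `gene:region_class`, where the class is `"hotspot"` (only the exons where
#' the gene's mutations cluster) or `"whole_exon"` (the full coding region).
#' A bare gene name defaults to `"hotspot"`.
#'
#' @param path Path to a BED file with at least 4 tab-separated columns
#'   (chrom, start, end, name). Lines starting with `#` or `track` are
#'   skipped.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open, as in the file) and `region_class`, sorted by
#'   `(chrom, start)`. Duplicate intervals are rejected.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr17\t7571000\t7590000\tTP53:whole_exon", bed)
#' read_panel_bed(bed)
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("panel BED not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) abort(sprintf("panel BED is empty: %s", path))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)

  bad_ncol <- line_no[lengths(fields) < 4]
  if (length(bad_ncol) > 0) {
    abort(sprintf("panel BED needs >= 4 columns; malformed line(s): %s",
                  paste(bad_ncol, collapse = ", ")))
  }

  chrom <- vapply(fields, `[[`, character(1), 1)
  start_raw <- vapply(fields, `[[`, character(1), 2)
  end_raw <- vapply(fields, `[[`, character(1), 3)
  name <- vapply(fields, `[[`, character(1), 4)

  start <- suppressWarnings(as.integer(start_raw))
  end <- suppressWarnings(as.integer(end_raw))
  bad_int <- line_no[is.na(start) | is.na(end)]
  if (length(bad_int) > 0) {
    abort(sprintf("non-integer coordinates on line(s): %s",
                  paste(bad_int, collapse = ", ")))
  }
  bad_iv <- line_no[start >= end]
  if (length(bad_iv) > 0) {
    abort(sprintf("start >= end (empty interval) on line(s): %s",
                  paste(bad_iv, collapse = ", ")))
  }

  gene <- sub(":.*$", "", name)
  region_class <- ifelse(grepl(":", name, fixed = TRUE),
                         sub("^[^:]*:", "", name), "hotspot")
  bad_class <- line_no[!region_class %in% c("hotspot", "whole_exon")]
  if (length(bad_class) > 0) {
    abort(sprintf(
      "region class must be 'hotspot' or 'whole_exon'; bad line(s): %s",
      paste(bad_class, collapse = ", ")))
  }

  panel <- tibble(
    gene = gene, chrom = normalize_chrom(chrom),
    start = start, end = end, region_class = region_class
  )
  if (anyDuplicated(panel[c("chrom", "start", "end")]) > 0) {
    abort("duplicate panel intervals by (chrom, start, end)")
  }
  dplyr::arrange(panel, .data$chrom, .data$start)
}

#' Write a panel to BED
#'
#' Inverse of [read_panel_bed()]: writes `gene:region_class` into the BED
#' name column.
#'
#' @param panel Panel tibble as returned by [read_panel_bed()] or
#'   [simulate_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(all(c("gene", "chrom", "start", "end", "region_class") %in% names(panel)))
  lines <- sprintf("%s\t%d\t%d\t%s:%s", panel$chrom, panel$start, panel$end,
                   panel$gene, panel$region_class)
  writeLines(lines, path)
  invisible(path)
}

#' Map pileup positions to panel genes
#'
#' Assigns to each (chrom, 1-based pos) pair the gene of the covering panel
#' interval, or `NA` where no interval covers the position.
#'
#' @param chrom,pos Vectors of chromosome labels and 1-based positions.
#' @param panel Panel tibble.
#' @return Character vector of gene symbols.
#' @keywords internal
panel_gene_at <- function(chrom, pos, panel) {
  chrom <- normalize_chrom(chrom)
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(panel))) {
    hit <- chrom == panel$chrom[i] & pos > panel$start[i] & pos <= panel$end[i]
    out[hit & is.na(out)] <- panel$gene[i]
  }
  out
}

#' Generate a synthetic targeted panel
#'
#' Builds a panel of contiguous single-base loci grouped into gene-sized
#' intervals, for use with [simulate_pair()]. Genes alternate between
#' hotspot and whole-exon design so both region classes are represented.
#'
#' @param n_loci Total number of targetable single-base positions.
#' @param n_genes Number of gene intervals the loci are split across.
#' @return A panel tibble (see [read_panel_bed()]).
#' @examples
#' simulate_panel(n_loci = 100, n_genes = 4)
#' @export
simulate_panel <- function(n_loci = 2000, n_genes = 20) {
  stopifnot(n_loci >= n_genes, n_genes >= 1)
  per_gene <- diff(round(seq(0, n_loci, length.out = n_genes + 1)))
  start <- 1000L + 10000L * (seq_len(n_genes) - 1L)
  tibble(
    gene = sprintf("GENE%02d", seq_len(n_genes)),
    chrom = paste0("chr", ((seq_len(n_genes) - 1L) %% 5L) + 1L),
    start = start,
    end = start + as.integer(per_gene),
    region_class = rep_len(c("hotspot", "whole_exon"), n_genes)
  ) %>% dplyr::arrange(.data$chrom, .data$start)
}
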