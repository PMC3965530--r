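#' Summarize a mutation landscape
#'
#' Aggregates an annotated mutation table into per-gene and per-patient
#' summaries and the gene-by-patient mutation-count matrix. Two per-gene
#' quantities are reported, because they differ: `n_mutations` counts
#' mutation rows ("times mutated", preserving multiplicity when a patient
#' carries two mutations in the same gene), while `patients_mutated` counts
#' distinct patients with at least one mutation, and `percent_patients` is
#' `100 * patients_mutated / n_patients` — the gene "mutation rate" by
#' which genes are ranked.
#'
#' @param table Mutation table ([read_mutation_table()]).
#' @param n_patients Cohort size (>= number of distinct samples in the
#'   table; patients without mutations enter the denominator even though
#'   they have no rows).
#' @return An object of class `cohort_summary`: a list with `per_gene`
#'   (ranked by `percent_patients` descending, ties alphabetical),
#'   `per_patient`, `matrix` (tibble, genes x observed patients) and
#'   `n_patients`.
#' @examples
#' tbl <- read_mutation_table(system.file("extdata", "hnscc_mutations.tsv",
#'                                        package = "somaticpair"))
#' s <- summarize_mutations(tbl, n_patients = 37)
#' tidy(s)    # per-gene summary, TP53 first
#' glance(s)
#' @export
summarize_mutations <- function(table, n_patients) {
  samples <- unique(table$sample_id)
  if (n_patients < length(samples)) {
    abort(sprintf("n_patients (%d) < %d distinct samples observed",
                  n_patients, length(samples)))
  }
  per_gene <- table %>%
    dplyr::group_by(gene = .data$gene) %>%
    dplyr::summarise(
      n_mutations = dplyr::n(),
      patients_mutated = dplyr::n_distinct(.data$sample_id),
      .groups = "drop") %>%
    dplyr::mutate(percent_patients = 100 * .data$patients_mutated / n_patients) %>%
    dplyr::arrange(dplyr::desc(.data$percent_patients), .data$gene)

  # patients ordered by their numeric suffix when ids look like X12
  sample_order <- function(ids) {
    num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", ids)))
    if (any(is.na(num))) sort(ids) else ids[order(num)]
  }
  samples <- sample_order(samples)

  per_patient <- table %>%
    dplyr::count(sample_id = .data$sample_id, name = "n_mutations") %>%
    dplyr::arrange(match(.data$sample_id, samples))

  mat <- table %>%
    dplyr::count(.data$gene, .data$sample_id) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L) %>%
    dplyr::arrange(match(.data$gene, per_gene$gene))
  mat <- mat[, c("gene", intersect(samples, names(mat)))]

  structure(list(per_gene = per_gene, per_patient = per_patient,
                 matrix = mat, n_patients = as.integer(n_patients)),
            class = "cohort_summary")
}

#' @method print cohort_summary
#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Mutation landscape: %d mutations in %d genes across %d/%d patients\n",
              sum(x$per_gene$n_mutations), nrow(x$per_gene),
              nrow(x$per_patient), x$n_patients))
  print(x$per_gene, ...)
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 contingency table,
#' computed by summing the hypergeometric probabilities of all tables (at
#' the observed margins) no more probable than the observed one — the
#' probability-mass-summation definition, not the doubled one-sided tail.
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(1, 1, 1, 1), 2))  # 1
#' fisher_exact(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) abort("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  if (sum(m) == 0) abort("all-zero table")
  fisher.test(m)$p.value
}

#' Compare mutation burden between two patient groups
#'
#' Given per-patient mutation burdens and a two-level grouping, reports
#' each group's mean mutations/sample, the fold difference (larger over
#' smaller; infinite when one mean is zero and the other is not; 1 when
#' both are zero), and a Fisher exact test on the 2x2 table of (any
#' mutation vs none) by group. Patients with a missing group label are
#' excluded from the comparison only.
#'
#' @param data Tibble with one row per patient.
#' @param burden Column of mutation counts (tidy-selected).
#' @param group Column with exactly two distinct non-missing labels.
#' @return An object of class `group_comparison`; see [tidy()] /
#'   [glance()] methods.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_patients = 200, seed = 2))
#' d <- dplyr::left_join(cohort$clinical, cohort$burdens, by = "sample_id")
#' glance(group_burden(d, n_mutations, smoker))
#' @export
group_burden <- function(data, burden, group) {
  b <- dplyr::pull(data, {{ burden }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(g) & !is.na(b)
  b <- b[keep]
  g <- as.character(g[keep])
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    abort(sprintf("need exactly two group labels, got: %s",
                  paste(levels, collapse = ", ")))
  }
  if (any(table(g) == 0)) abort("a group has zero members")
  means <- vapply(levels, function(l) mean(b[g == l]), numeric(1))
  fold <- if (max(means) == 0) 1
  else if (min(means) == 0) Inf
  else max(means) / min(means)
  tab <- rbind(mutated = c(sum(b[g == levels[1]] > 0),
                           sum(b[g == levels[2]] > 0)),
               unmutated = c(sum(b[g == levels[1]] == 0),
                             sum(b[g == levels[2]] == 0)))
  colnames(tab) <- levels
  structure(list(
    groups = levels, n = unname(table(g)[levels]), means = means,
    fold = fold, table = tab,
    fisher_p = if (sum(tab) > 0) fisher_exact(tab) else NA_real_
  ), class = "group_comparison")
}

#' @method print group_comparison
#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Burden comparison %s vs %s: means %.3g vs %.3g (fold %.3g), Fisher p = %.3g\n",
    x$groups[1], x$groups[2], x$means[1], x$means[2], x$fold, x$fisher_p))
  invisible(x)
}

#' Per-group mutation rate of one gene
#'
#' For a single gene, computes each group's mutations per sample (mutation
#' rows in the group divided by group size) and the ratio of rates,
#' oriented larger over smaller (`rate_ratio`); the signed orientation is
#' recoverable from the per-group rows. A zero rate in one group gives an
#' infinite ratio.
#'
#' @param table Mutation table.
#' @param clinical Tibble with `sample_id` and the grouping column; defines
#'   group membership and size. Patients with a missing label are excluded.
#' @param gene Gene symbol to summarise.
#' @param group Grouping column (tidy-selected, two levels).
#' @return A tibble with one row per group (`group`, `n_samples`,
#'   `n_mutations`, `rate`) and attribute `rate_ratio`.
#' @export
gene_rate_by_group <- function(table, clinical, gene, group) {
  g <- dplyr::pull(clinical, {{ group }})
  keep <- !is.na(g)
  clinical <- clinical[keep, ]
  g <- as.character(g[keep])
  levels <- sort(unique(g))
  if (length(levels) != 2) abort("need exactly two group labels")
  rows <- table[table$gene == gene, ]
  out <- purrr::map_dfr(levels, function(l) {
    ids <- clinical$sample_id[g == l]
    if (length(ids) == 0) abort(sprintf("empty group %s", l))
    k <- sum(rows$sample_id %in% ids)
    tibble(group = l, n_samples = length(ids), n_mutations = k,
           rate = k / length(ids))
  })
  rates <- out$rate
  attr(out, "rate_ratio") <- if (max(rates) == 0) 1
  else if (min(rates) == 0) Inf
  else max(rates) / min(rates)
  out
}

#' Export the gene-by-patient mutation matrix
#'
#' Writes the landscape matrix as TSV: genes as rows ranked by percent of
#' patients mutated (descending, ties alphabetical), patients as columns,
#' integer mutation counts in cells, and a final `TOTAL` row of per-patient
#' burdens. The grand total equals the mutation table's row count.
#'
#' @param summary A [summarize_mutations()] result.
#' @param path Output TSV path.
#' @return The exported tibble (including the `TOTAL` row), invisibly.
#' @export
export_matrix <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  mat <- summary$matrix
  totals <- dplyr::summarise(mat, gene = "TOTAL",
                             dplyr::across(-"gene", sum))
  out <- dplyr::bind_rows(mat, totals)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
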