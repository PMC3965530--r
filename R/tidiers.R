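#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-unit table (per candidate call, per gene, per group), `glance()`
#' a one-row summary.
#'
#' @param x A `somatic_calls`, `cohort_summary` or `group_comparison`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name somaticpair-tidiers
NULL

#' @rdname somaticpair-tidiers
#' @method tidy somatic_calls
#' @export
tidy.somatic_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "somatic_calls")
  attr(out, "attrition") <- NULL
  attr(out, "background_cutoff") <- NULL
  attr(out, "config") <- NULL
  as_tibble(out)
}

#' @rdname somaticpair-tidiers
#' @method glance somatic_calls
#' @export
glance.somatic_calls <- function(x, ...) {
  a <- attr(x, "attrition")
  tibble(
    n_loci = unname(a["loci"]), n_retained = unname(a["retained"]),
    n_candidates = unname(a["candidates"]),
    n_low_coverage = unname(a["low_coverage"]),
    n_low_vaf = unname(a["low_vaf"]),
    n_blacklist = unname(a["blacklist"]),
    n_germline = unname(a["germline"]),
    n_systematic = unname(a["systematic"]),
    n_accepted = unname(a["accepted"]),
    background_cutoff = attr(x, "background_cutoff")
  )
}

#' @rdname somaticpair-tidiers
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) x$per_gene

#' @rdname somaticpair-tidiers
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    n_patients_mutated = nrow(x$per_patient),
    n_genes = nrow(x$per_gene),
    n_mutations = sum(x$per_gene$n_mutations),
    percent_patients_mutated =
      100 * nrow(x$per_patient) / x$n_patients
  )
}

#' @rdname somaticpair-tidiers
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(
    group = x$groups, n = as.integer(x$n),
    mean_burden = unname(x$means),
    n_mutated = unname(x$table["mutated", ]),
    n_unmutated = unname(x$table["unmutated", ])
  )
}

#' @rdname somaticpair-tidiers
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    group1 = x$groups[1], group2 = x$groups[2],
    mean1 = unname(x$means[1]), mean2 = unname(x$means[2]),
    fold = x$fold, fisher_p = x$fisher_p
  )
}
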