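#' Plot a mutation landscape (oncoprint-style)
#'
#' Gene-by-patient tile plot of mutation counts, genes ranked by the
#' percent of patients mutated (top = most frequently mutated), patients in
#' cohort order. Cells with two mutations in the same gene are labelled.
#'
#' @param object A [summarize_mutations()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object$matrix, -"gene",
                              names_to = "sample_id", values_to = "n")
  long$gene <- factor(long$gene, levels = rev(object$per_gene$gene))
  long$sample_id <- factor(long$sample_id,
                           levels = names(object$matrix)[-1])
  ggplot2::ggplot(long[long$n > 0, ],
                  ggplot2::aes(x = .data$sample_id, y = .data$gene)) +
    ggplot2::geom_tile(fill = "grey15", colour = "white") +
    ggplot2::geom_text(data = ~ dplyr::filter(.x, .data$n > 1),
                       ggplot2::aes(label = .data$n), colour = "white",
                       size = 3) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(x = "patient", y = NULL,
                  title = "Mutation landscape",
                  subtitle = sprintf("%d mutations, %d genes, %d/%d patients",
                                     sum(object$per_gene$n_mutations),
                                     nrow(object$per_gene),
                                     nrow(object$per_patient),
                                     object$n_patients)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Plot candidate calls in VAF space
#'
#' Tumor vs normal variant allele fraction for every nominated candidate,
#' coloured by filter outcome. Accepted somatic calls sit high on the tumor
#' axis and near zero on the normal axis; germline variants track the
#' diagonal; systematic artifacts cluster at low VAF in both samples.
#'
#' @param object A `somatic_calls` tibble from [call_somatic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot somatic_calls
#' @export
autoplot.somatic_calls <- function(object, ...) {
  d <- tidy(object)
  d$outcome <- ifelse(d$accepted, "accepted",
                      vapply(strsplit(d$filters, ";"), `[[`, character(1), 1))
  cfg <- attr(object, "config")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$normal_vaf, y = .data$tumor_vaf,
                                  colour = .data$outcome)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = cfg$tumor_vaf_min, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = cfg$normal_vaf_max, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "normal VAF", y = "tumor VAF", colour = "outcome",
                  title = "Candidate variants and filter outcomes") +
    ggplot2::theme_minimal()
}

#' Plot a group burden comparison
#'
#' Bar chart of the two group means with the fold difference and Fisher
#' exact p in the subtitle.
#'
#' @param object A [group_burden()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean_burden)) +
    ggplot2::geom_col(fill = "grey25", width = 0.6) +
    ggplot2::labs(x = NULL, y = "mean mutations / sample",
                  title = "Mutation burden by group",
                  subtitle = sprintf("fold = %.2f, Fisher p = %.3g",
                                     object$fold, object$fisher_p)) +
    ggplot2::theme_minimal()
}
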