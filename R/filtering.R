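#' Filter cascade configuration
#'
#' Thresholds of the somatic calling cascade. Defaults reproduce the
#' published rules: a locus is retained only when its depth exceeds both
#' `min_reads` (100) and `median_fraction` (2%) of the sample median
#' coverage; a candidate needs tumor VAF at or above `tumor_vaf_min` (the
#' 6% mutation read frequency threshold); it is flagged as germline when the
#' matched normal shows strictly more than `normal_vaf_max` (1%) variant
#' reads; and it is flagged as systematic when its tumor-minus-normal
#' variant score difference is within the `diff_percentile` (99.5th)
#' percentile of pairwise differences over background loci.
#'
#' @param min_reads Minimum read depth (strict `>`), per sample.
#' @param median_fraction Fraction of the sample median coverage a locus
#'   must exceed (strict `>`), per sample.
#' @param tumor_vaf_min Tumor variant allele fraction call threshold
#'   (inclusive `>=`: a variant exactly at the threshold is callable).
#' @param normal_vaf_max Maximum normal VAF before a candidate is flagged
#'   germline (strict `>` flags).
#' @param diff_percentile Percentile (in percent) of the background
#'   score-difference distribution below which candidates are flagged
#'   systematic; ties at the percentile are flagged.
#' @param background_error Background per-base error rate used by the
#'   Phred-scaled binomial variant score.
#' @param candidate_vaf_min Nomination floor: loci whose tumor VAF reaches
#'   this fraction enter the candidate list (and are excluded from the
#'   background distribution); candidates between this floor and
#'   `tumor_vaf_min` are reported with the `low_vaf` flag rather than
#'   silently dropped. Must not exceed `tumor_vaf_min`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_reads = 100, median_fraction = 0.02,
                          tumor_vaf_min = 0.06, normal_vaf_max = 0.01,
                          diff_percentile = 99.5, background_error = 0.005,
                          candidate_vaf_min = 0.02) {
  stopifnot(
    is.finite(min_reads), min_reads >= 0,
    is.finite(median_fraction), median_fraction >= 0, median_fraction <= 1,
    is.finite(tumor_vaf_min), tumor_vaf_min >= 0, tumor_vaf_min <= 1,
    is.finite(normal_vaf_max), normal_vaf_max >= 0, normal_vaf_max <= 1,
    is.finite(diff_percentile), diff_percentile > 0, diff_percentile < 100,
    is.finite(background_error), background_error > 0, background_error < 1,
    is.finite(candidate_vaf_min), candidate_vaf_min >= 0,
    candidate_vaf_min <= tumor_vaf_min
  )
  structure(list(
    min_reads = min_reads, median_fraction = median_fraction,
    tumor_vaf_min = tumor_vaf_min, normal_vaf_max = normal_vaf_max,
    diff_percentile = diff_percentile, background_error = background_error,
    candidate_vaf_min = candidate_vaf_min
  ), class = "filter_config")
}

#' Sample median coverage
#'
#' Median of the per-locus read depth of one sample; for an even number of
#' loci, the mean of the two middle order statistics.
#'
#' @param pileup Pileup tibble (non-empty).
#' @return A single number of reads.
#' @export
sample_median_coverage <- function(pileup) {
  check_pileup(pileup)
  median(pileup$depth)
}

#' Coverage retention gate
#'
#' A locus is retained when its depth strictly exceeds both arms of the
#' high-coverage rule: `median_fraction` of the sample median coverage and
#' `min_reads` reads.
#'
#' @param pileup Pileup tibble.
#' @param median_cov Median coverage of the same sample
#'   ([sample_median_coverage()]).
#' @param config A [filter_config()].
#' @return Logical vector, one element per pileup row; `TRUE` = retained.
#' @export
coverage_gate <- function(pileup, median_cov, config = filter_config()) {
  check_pileup(pileup)
  pileup$depth > config$median_fraction * median_cov &
    pileup$depth > config$min_reads
}

#' Phred-scaled binomial variant score
#'
#' Scores the evidence that the alternate reads at a locus exceed what the
#' background error rate explains: `-10 * log10 P[X >= alt]` for
#' `X ~ Binomial(depth, background_error)`. Zero alternate reads score 0
#' (the upper tail has probability one); the score is monotone
#' non-decreasing in `alt` at fixed depth. Computed in log space so deep
#' loci with many alternate reads do not overflow.
#'
#' @param depth,alt Integer vectors of total and alternate read counts
#'   (`0 <= alt <= depth`).
#' @param background_error Background per-base error rate in (0, 1).
#' @return Numeric vector of scores (Phred-like units).
#' @examples
#' variant_score(100, 1, 0.005)   # about 4.04
#' variant_score(1000, 80, 0.005) # large: strong variant evidence
#' @export
variant_score <- function(depth, alt, background_error = 0.005) {
  if (any(alt > depth)) abort("alt reads exceed depth")
  if (any(alt < 0) || any(depth < 0)) abort("negative read counts")
  stopifnot(background_error > 0, background_error < 1)
  logp <- pbinom(alt - 1, depth, background_error,
                 lower.tail = FALSE, log.p = TRUE)
  s <- -10 * logp / log(10)
  s[alt == 0] <- 0
  s
}

#' Germline flag for a candidate locus
#'
#' A candidate is flagged as a putative germline variant when the matched
#' normal carries strictly more than `normal_vaf_max` variant reads at the
#' same alternate base. A normal with zero depth cannot exclude a germline
#' origin and is flagged conservatively.
#'
#' @param normal_depth,normal_alt Read counts in the matched normal at the
#'   candidate's alternate base.
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` = flagged germline.
#' @export
germline_flagged <- function(normal_depth, normal_alt,
                             config = filter_config()) {
  ifelse(normal_depth == 0, TRUE,
         normal_alt / normal_depth > config$normal_vaf_max)
}

# Most frequent non-reference base per locus from a count matrix;
# ties broken alphabetically (A < C < G < T).
top_alt_base <- function(counts, ref_base) {
  counts <- as.matrix(counts)
  colnames(counts) <- BASES
  ref_idx <- match(ref_base, BASES)
  counts[cbind(seq_len(nrow(counts)), ref_idx)] <- -1L
  # max.col with ties.method "first" picks the alphabetically first base
  idx <- max.col(counts, ties.method = "first")
  alt <- BASES[idx]
  alt_count <- counts[cbind(seq_len(nrow(counts)), idx)]
  alt_count[alt_count < 0] <- 0L
  list(base = alt, count = as.integer(alt_count))
}

# Join a matched pair into one per-locus table with tumor_/normal_ columns.
join_pair <- function(tumor, normal) {
  check_pileup(tumor, "tumor")
  check_pileup(normal, "normal")
  t_loci <- paste(tumor$chrom, tumor$pos)
  n_loci <- paste(normal$chrom, normal$pos)
  if (length(t_loci) != length(n_loci) || !setequal(t_loci, n_loci)) {
    abort("tumor and normal pileups cover different loci (mismatched panels)")
  }
  if (!identical(sort(paste(t_loci, tumor$ref_base)),
                 sort(paste(n_loci, normal$ref_base)))) {
    abort("tumor and normal disagree on reference bases")
  }
  dplyr::inner_join(
    dplyr::rename_with(tumor, ~ paste0("tumor_", .x),
                       dplyr::all_of(c("depth", "count_A", "count_C",
                                       "count_G", "count_T"))) %>%
      dplyr::select(-"sample_id"),
    dplyr::rename_with(normal, ~ paste0("normal_", .x),
                       dplyr::all_of(c("depth", "count_A", "count_C",
                                       "count_G", "count_T"))) %>%
      dplyr::select(-"sample_id"),
    by = c("chrom", "pos", "ref_base")
  )
}

#' Background distribution of variant score differences
#'
#' For every retained locus that is neither a nominated candidate nor
#' blacklisted, computes the tumor-minus-normal difference of Phred-scaled
#' variant scores at the locus's most frequent non-reference base (counts
#' pooled over both samples; ties alphabetical). These loci carry no called
#' variant signal, so the distribution of their pairwise differences
#' characterises sample-specific systematic error, against which candidate
#' score differences are judged.
#'
#' @param pair Joined pair table from the cascade (one row per locus with
#'   `tumor_*` and `normal_*` count columns).
#' @param retained Logical vector: locus passed the coverage gate in both
#'   samples.
#' @param candidate Logical vector: locus is a nominated candidate.
#' @param blacklisted Logical vector: locus is on the blacklist.
#' @param config A [filter_config()].
#' @return Sorted numeric vector of score differences. Fewer than 200
#'   background loci is an error: the extreme percentile would be unstable.
#' @export
background_difference_distribution <- function(pair, retained, candidate,
                                               blacklisted,
                                               config = filter_config()) {
  bg <- retained & !candidate & !blacklisted
  if (sum(bg) < 200) {
    abort(sprintf(
      "only %d background loci; need >= 200 for a stable %.1f%% percentile",
      sum(bg), config$diff_percentile))
  }
  b <- pair[bg, ]
  pooled <- b[c("tumor_count_A", "tumor_count_C",
                "tumor_count_G", "tumor_count_T")] +
    b[c("normal_count_A", "normal_count_C",
        "normal_count_G", "normal_count_T")]
  alt <- top_alt_base(pooled, b$ref_base)
  base_idx <- match(alt$base, BASES)
  t_counts <- as.matrix(b[c("tumor_count_A", "tumor_count_C",
                            "tumor_count_G", "tumor_count_T")])
  n_counts <- as.matrix(b[c("normal_count_A", "normal_count_C",
                            "normal_count_G", "normal_count_T")])
  rows <- seq_len(nrow(b))
  t_alt <- t_counts[cbind(rows, base_idx)]
  n_alt <- n_counts[cbind(rows, base_idx)]
  diffs <- variant_score(b$tumor_depth, t_alt, config$background_error) -
    variant_score(b$normal_depth, n_alt, config$background_error)
  sort(diffs)
}

#' Systematic-error flag from the background percentile
#'
#' A candidate is flagged as sample-specific systematic error when its
#' variant score difference lies within (at or below) the configured
#' percentile of the background difference distribution. The percentile is
#' computed by linear interpolation between the closest order statistics
#' (`stats::quantile()` type 7), so results are bit-reproducible.
#'
#' @param score_diff Numeric vector of candidate score differences.
#' @param background Numeric vector from
#'   [background_difference_distribution()] (non-empty).
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` = flagged systematic.
#' @export
systematic_flagged <- function(score_diff, background,
                               config = filter_config()) {
  if (length(background) == 0) abort("empty background distribution")
  cut <- quantile(background, config$diff_percentile / 100,
                  type = 7, names = FALSE)
  score_diff <= cut
}

#' Call somatic mutations on a matched tumor/normal pair
#'
#' Runs the full filter cascade:
#' 1. coverage gate in both samples (each against its own median coverage);
#' 2. candidate nomination: loci whose most frequent non-reference tumor
#'    base reaches `candidate_vaf_min`, with `low_vaf` flagged below the
#'    `tumor_vaf_min` call threshold and `low_coverage` flagged where
#'    either sample fails its gate;
#' 3. blacklist flag for known systematic positives;
#' 4. germline flag from the matched normal;
#' 5. systematic flag against the background score-difference percentile.
#'
#' Every nominated candidate is returned with its flags; a call is accepted
#' exactly when its flag set is empty.
#'
#' @param tumor,normal Pileup tibbles over the same loci.
#' @param panel Optional panel tibble; when given, calls are annotated with
#'   the covering gene.
#' @param blacklist Optional blacklist tibble (`chrom`, `pos`).
#' @param config A [filter_config()].
#' @return A tibble of class `somatic_calls`, one row per candidate, with
#'   tumor/normal depths, alternate counts and VAFs, `score_diff`,
#'   `filters` (semicolon-joined flags, `""` when accepted) and `accepted`.
#'   Attributes record the per-filter attrition counts and the background
#'   percentile cutoff.
#' @examples
#' panel <- simulate_panel(400, 4)
#' sim <- simulate_pair(panel, sim_params(n_loci = 400, n_somatic = 2,
#'                                        n_germline = 3, n_artifact_loci = 2,
#'                                        seed = 7))
#' calls <- call_somatic(sim$tumor, sim$normal, panel)
#' dplyr::filter(calls, accepted)
#' @export
call_somatic <- function(tumor, normal, panel = NULL, blacklist = NULL,
                         config = filter_config()) {
  pair <- join_pair(tumor, normal)

  med_t <- median(pair$tumor_depth)
  med_n <- median(pair$normal_depth)
  retained <- pair$tumor_depth > config$median_fraction * med_t &
    pair$tumor_depth > config$min_reads &
    pair$normal_depth > config$median_fraction * med_n &
    pair$normal_depth > config$min_reads

  t_alt <- top_alt_base(pair[c("tumor_count_A", "tumor_count_C",
                               "tumor_count_G", "tumor_count_T")],
                        pair$ref_base)
  tumor_vaf <- ifelse(pair$tumor_depth > 0,
                      t_alt$count / pair$tumor_depth, 0)
  candidate <- t_alt$count > 0 & tumor_vaf >= config$candidate_vaf_min

  blacklisted <- rep(FALSE, nrow(pair))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    blacklisted <- paste(pair$chrom, pair$pos) %in%
      paste(normalize_chrom(blacklist$chrom), blacklist$pos)
  }

  background <- background_difference_distribution(
    pair, retained, candidate, blacklisted, config)

  calls <- pair[candidate, ]
  alt_base <- t_alt$base[candidate]
  base_idx <- match(alt_base, BASES)
  rows <- seq_len(nrow(calls))
  n_counts <- as.matrix(calls[c("normal_count_A", "normal_count_C",
                                "normal_count_G", "normal_count_T")])
  tumor_alt <- t_alt$count[candidate]
  normal_alt <- n_counts[cbind(rows, base_idx)]

  score_diff <- variant_score(calls$tumor_depth, tumor_alt,
                              config$background_error) -
    variant_score(calls$normal_depth, normal_alt, config$background_error)

  flag <- tibble(
    low_coverage = !retained[candidate],
    low_vaf = tumor_vaf[candidate] < config$tumor_vaf_min,
    blacklist = blacklisted[candidate],
    germline = germline_flagged(calls$normal_depth, normal_alt, config),
    systematic = systematic_flagged(score_diff, background, config)
  )
  # alphabetical flag order within the joined string
  flag <- flag[, sort(names(flag))]
  filters <- apply(as.matrix(flag), 1, function(f) {
    paste(names(flag)[f], collapse = ";")
  })
  if (nrow(calls) == 0) filters <- character(0)

  out <- tibble(
    gene = if (!is.null(panel)) {
      panel_gene_at(calls$chrom, calls$pos, panel)
    } else NA_character_,
    chrom = calls$chrom, pos = calls$pos, ref_base = calls$ref_base,
    alt_base = alt_base,
    tumor_depth = calls$tumor_depth, tumor_alt = tumor_alt,
    tumor_vaf = tumor_vaf[candidate],
    normal_depth = calls$normal_depth, normal_alt = as.integer(normal_alt),
    normal_vaf = ifelse(calls$normal_depth > 0,
                        normal_alt / calls$normal_depth, NA_real_),
    score_diff = score_diff,
    filters = filters,
    accepted = !nzchar(filters)
  ) %>% dplyr::arrange(.data$chrom, .data$pos)

  attr(out, "attrition") <- c(
    loci = nrow(pair), retained = sum(retained), candidates = nrow(calls),
    vapply(flag, sum, integer(1)), accepted = sum(out$accepted))
  attr(out, "background_cutoff") <- quantile(
    background, config$diff_percentile / 100, type = 7, names = FALSE)
  attr(out, "config") <- config
  class(out) <- c("somatic_calls", class(out))
  out
}

#' Benchmark accepted calls against a simulation truth table
#'
#' Tallies the confusion matrix of accepted calls against the planted
#' somatic loci of a [simulate_pair()] truth table. True positives are
#' accepted calls at truth-somatic loci; false positives are accepted calls
#' anywhere else; false negatives are truth-somatic loci without an
#' accepted call.
#'
#' @param calls A `somatic_calls` tibble.
#' @param truth Truth tibble from [simulate_pair()].
#' @param n_loci Optional total number of assessed loci; when given,
#'   specificity is reported over the `n_loci - n_somatic` negative loci.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `sensitivity`, `ppv`
#'   (`NA` when no call is accepted) and `specificity` (`NA` when `n_loci`
#'   is not supplied).
#' @export
recovery_metrics <- function(calls, truth, n_loci = NULL) {
  somatic <- truth[truth$class == "somatic", ]
  somatic_key <- paste(somatic$chrom, somatic$pos)
  accepted <- calls[calls$accepted, ]
  accepted_key <- paste(accepted$chrom, accepted$pos)
  tp <- sum(accepted_key %in% somatic_key)
  fp <- sum(!accepted_key %in% somatic_key)
  fn <- sum(!somatic_key %in% accepted_key)
  tibble(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    specificity = if (!is.null(n_loci)) {
      tn <- n_loci - length(somatic_key) - fp
      tn / (tn + fp)
    } else NA_real_
  )
}
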