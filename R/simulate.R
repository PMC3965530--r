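#' Simulation parameters for a matched pileup pair
#'
#' Declares the statistical structure of one simulated tumor/normal pair.
#' Coverage is negative-binomially overdispersed around the target median
#' (targeted amplicon coverage is markedly non-Poisson); sequencing errors
#' are binomial at a fixed per-locus rate; germline heterozygous variants
#' appear in both samples at allele fraction ~0.5; somatic variants appear
#' in the tumor only at an allele fraction drawn uniformly from
#' `somatic_vaf_range`; artifact loci carry an elevated, shared error rate
#' in both samples, mimicking systematic positives.
#'
#' Defaults define the package's reference benchmark: 2000 loci at median
#' coverage 1000 (dispersion 10), base error 0.2%, 5 somatic variants with
#' VAF in \[0.08, 0.5\] (comfortably above the 6% call threshold and
#' spanning orthogonally validated read frequencies of 14--46%),
#' 20 heterozygous germline variants, 10 artifact loci at 2% error.
#'
#' @param n_loci Number of single-base loci to simulate.
#' @param median_coverage Target mean/median read depth.
#' @param coverage_dispersion Negative-binomial size parameter; `Inf` gives
#'   constant depth exactly equal to `median_coverage`.
#' @param base_error_rate Mean per-locus sequencing error rate in `[0, 1)`.
#' @param n_germline Number of heterozygous germline loci.
#' @param germline_het_vaf Target heterozygous allele fraction (0.5).
#' @param n_germline_hom Number of homozygous germline loci (VAF 1);
#'   defaults to 0 — the germline filter treats het and hom identically.
#' @param n_somatic Number of planted somatic variants (tumor only).
#' @param somatic_vaf_range Length-2 vector `[low, high]` of somatic VAFs.
#' @param n_artifact_loci Number of shared systematic-artifact loci.
#' @param artifact_error_rate Error rate at artifact loci; must exceed
#'   `base_error_rate`.
#' @param low_coverage_fraction Fraction of loci forced below the retention
#'   thresholds (depth drawn uniformly in `[0, min(100, 2% of median)]` in
#'   both samples).
#' @param seed Integer seed; identical parameters give bitwise-identical
#'   output.
#' @return A list of class `sim_params`.
#' @seealso [simulate_pair()]
#' @export
sim_params <- function(n_loci = 2000, median_coverage = 1000,
                       coverage_dispersion = 10, base_error_rate = 0.002,
                       n_germline = 20, germline_het_vaf = 0.5,
                       n_germline_hom = 0, n_somatic = 5,
                       somatic_vaf_range = c(0.08, 0.5),
                       n_artifact_loci = 10, artifact_error_rate = 0.02,
                       low_coverage_fraction = 0.05, seed = 1) {
  num_ok <- function(x) is.numeric(x) && all(!is.na(x)) &&
    all(is.finite(x) | identical(x, Inf))
  stopifnot(
    num_ok(n_loci), n_loci >= 1,
    num_ok(median_coverage), median_coverage > 0,
    is.numeric(coverage_dispersion), !is.na(coverage_dispersion),
    coverage_dispersion > 0,
    num_ok(base_error_rate), base_error_rate >= 0, base_error_rate < 1,
    num_ok(n_germline), n_germline >= 0,
    num_ok(germline_het_vaf), germline_het_vaf >= 0, germline_het_vaf <= 1,
    num_ok(n_germline_hom), n_germline_hom >= 0,
    num_ok(n_somatic), n_somatic >= 0,
    length(somatic_vaf_range) == 2, num_ok(somatic_vaf_range),
    all(somatic_vaf_range >= 0), all(somatic_vaf_range <= 1),
    somatic_vaf_range[1] <= somatic_vaf_range[2],
    num_ok(n_artifact_loci), n_artifact_loci >= 0,
    num_ok(artifact_error_rate), artifact_error_rate > base_error_rate,
    artifact_error_rate < 1,
    num_ok(low_coverage_fraction), low_coverage_fraction >= 0,
    low_coverage_fraction <= 1,
    num_ok(seed)
  )
  structure(list(
    n_loci = as.integer(n_loci), median_coverage = median_coverage,
    coverage_dispersion = coverage_dispersion,
    base_error_rate = base_error_rate,
    n_germline = as.integer(n_germline),
    germline_het_vaf = germline_het_vaf,
    n_germline_hom = as.integer(n_germline_hom),
    n_somatic = as.integer(n_somatic),
    somatic_vaf_range = somatic_vaf_range,
    n_artifact_loci = as.integer(n_artifact_loci),
    artifact_error_rate = artifact_error_rate,
    low_coverage_fraction = low_coverage_fraction,
    seed = as.integer(seed)
  ), class = "sim_params")
}

draw_depth <- function(n, params) {
  if (is.infinite(params$coverage_dispersion)) {
    rep(as.integer(params$median_coverage), n)
  } else {
    rnbinom(n, size = params$coverage_dispersion,
            mu = params$median_coverage)
  }
}

# counts for one sample: alt reads at `vaf`, remainder on the ref base
assemble_counts <- function(ref_base, alt_base, depth, alt) {
  counts <- matrix(0L, nrow = length(depth), ncol = 4,
                   dimnames = list(NULL, BASES))
  rows <- seq_along(depth)
  counts[cbind(rows, match(alt_base, BASES))] <- as.integer(alt)
  ref_idx <- cbind(rows, match(ref_base, BASES))
  counts[ref_idx] <- counts[ref_idx] + as.integer(depth - alt)
  counts
}

#' Simulate a matched tumor/normal pileup pair
#'
#' Generates one pileup table per sample over the panel's positions, with a
#' ground-truth table of every planted event. Loci are assigned disjointly
#' to the somatic, germline (het/hom) and artifact classes; all remaining
#' loci carry base-rate errors only. See [sim_params()] for the generative
#' model.
#'
#' @param panel Panel tibble ([read_panel_bed()] / [simulate_panel()])
#'   whose intervals provide at least `n_loci` single-base positions.
#' @param params A [sim_params()] object.
#' @param tumor_id,normal_id Sample identifiers written into the tables.
#' @return A list with elements `tumor`, `normal` (pileup tibbles) and
#'   `truth`: one row per planted event with `chrom`, `pos`, `ref_base`,
#'   `alt_base`, `class` (`somatic`/`germline`/`artifact`) and `value` (the
#'   planted VAF, or error rate for artifacts).
#' @examples
#' panel <- simulate_panel(300, 3)
#' sim <- simulate_pair(panel, sim_params(n_loci = 300, seed = 42))
#' sim$truth
#' @export
simulate_pair <- function(panel, params = sim_params(),
                          tumor_id = "TUMOR", normal_id = "NORMAL") {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_loci
  n_planted <- params$n_somatic + params$n_germline +
    params$n_germline_hom + params$n_artifact_loci
  positions <- purrr::pmap(
    panel[c("chrom", "start", "end")],
    function(chrom, start, end) {
      tibble(chrom = chrom, pos = seq.int(start + 1L, end))
    }) %>% dplyr::bind_rows()
  if (nrow(positions) < n) {
    abort(sprintf("panel provides %d positions; %d loci requested",
                  nrow(positions), n))
  }
  if (nrow(panel) < n_planted && n_planted > n) {
    abort("more planted events than panel loci")
  }
  if (n_planted > n) abort("more planted events than simulated loci")

  withr::with_seed(params$seed, {
    loci <- positions[seq_len(n), ]
    loci$ref_base <- sample(BASES, n, replace = TRUE)
    # one alternate base per locus, never the reference
    shift <- sample(1:3, n, replace = TRUE)
    loci$alt_base <- BASES[(match(loci$ref_base, BASES) - 1L + shift) %% 4L + 1L]

    idx <- sample.int(n, n_planted)
    take <- function(k) {
      if (k == 0) return(integer(0))
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    i_som <- take(params$n_somatic)
    i_het <- take(params$n_germline)
    i_hom <- take(params$n_germline_hom)
    i_art <- take(params$n_artifact_loci)
    i_base <- setdiff(seq_len(n), c(i_som, i_het, i_hom, i_art))

    depth_t <- draw_depth(n, params)
    depth_n <- draw_depth(n, params)
    n_low <- floor(params$low_coverage_fraction * n)
    if (n_low > 0) {
      i_low <- sample(i_base, min(n_low, length(i_base)))
      cap <- as.integer(min(100, floor(0.02 * params$median_coverage)))
      depth_t[i_low] <- sample.int(cap + 1L, length(i_low),
                                   replace = TRUE) - 1L
      depth_n[i_low] <- sample.int(cap + 1L, length(i_low),
                                   replace = TRUE) - 1L
    }

    vaf_t <- rep(params$base_error_rate, n)
    vaf_n <- rep(params$base_error_rate, n)
    som_vaf <- runif(params$n_somatic, params$somatic_vaf_range[1],
                     params$somatic_vaf_range[2])
    vaf_t[i_som] <- som_vaf
    vaf_t[i_het] <- params$germline_het_vaf
    vaf_n[i_het] <- params$germline_het_vaf
    vaf_t[i_hom] <- 1
    vaf_n[i_hom] <- 1
    vaf_t[i_art] <- params$artifact_error_rate
    vaf_n[i_art] <- params$artifact_error_rate

    alt_t <- rbinom(n, depth_t, vaf_t)
    alt_n <- rbinom(n, depth_n, vaf_n)

    make_pileup <- function(sample_id, depth, alt) {
      counts <- assemble_counts(loci$ref_base, loci$alt_base, depth, alt)
      tibble(sample_id = sample_id, chrom = loci$chrom, pos = loci$pos,
             ref_base = loci$ref_base, depth = as.integer(depth),
             count_A = counts[, "A"], count_C = counts[, "C"],
             count_G = counts[, "G"], count_T = counts[, "T"])
    }
    tumor <- make_pileup(tumor_id, depth_t, alt_t)
    normal <- make_pileup(normal_id, depth_n, alt_n)

    truth_of <- function(i, class, value) {
      if (length(i) == 0) return(NULL)
      tibble(chrom = loci$chrom[i], pos = loci$pos[i],
             ref_base = loci$ref_base[i], alt_base = loci$alt_base[i],
             class = class, value = value)
    }
    truth <- dplyr::bind_rows(
      truth_of(i_som, "somatic", som_vaf),
      truth_of(i_het, "germline", params$germline_het_vaf),
      truth_of(i_hom, "germline", 1),
      truth_of(i_art, "artifact", params$artifact_error_rate)
    )
    if (nrow(truth) == 0) {
      truth <- tibble(chrom = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      class = character(), value = double())
    }
    list(tumor = tumor, normal = normal,
         truth = dplyr::arrange(truth, .data$chrom, .data$pos))
  })
}

#' Cohort-level simulation parameters
#'
#' Declares a cohort with smoking and HPV covariates and Poisson mutation
#' burdens. Non-smokers accrue `burden_mean_nonsmoker` mutations per sample
#' on average and smokers `burden_fold_smoker` times more; TP53 mutation
#' counts are Poisson with an HPV-stratified rate. Defaults reproduce the
#' cohort-level effect sizes observed in the 37-patient HNSCC study: a
#' 3.2-fold smoker excess over a non-smoker mean of 0.25 mutations/sample,
#' and TP53 rates of 0.43 (HPV-negative) vs 0.11 (HPV-positive)
#' mutations/sample, with 65% smokers and 24% HPV-positive patients.
#'
#' @param n_patients Number of patients (>= 2).
#' @param smoker_fraction,hpv_pos_fraction Covariate prevalences.
#' @param burden_mean_nonsmoker Mean mutations/sample among non-smokers.
#' @param burden_fold_smoker Multiplicative smoker effect (> 0).
#' @param tp53_rate_hpv_neg,tp53_rate_hpv_pos TP53 mutations/sample by HPV
#'   status.
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 37, smoker_fraction = 0.65,
                          hpv_pos_fraction = 0.24,
                          burden_mean_nonsmoker = 0.25,
                          burden_fold_smoker = 3.2,
                          tp53_rate_hpv_neg = 0.43,
                          tp53_rate_hpv_pos = 0.11, seed = 1) {
  stopifnot(
    n_patients >= 2,
    smoker_fraction >= 0, smoker_fraction <= 1,
    hpv_pos_fraction >= 0, hpv_pos_fraction <= 1,
    burden_mean_nonsmoker >= 0, burden_fold_smoker > 0,
    tp53_rate_hpv_neg >= 0, tp53_rate_hpv_pos >= 0,
    is.finite(seed)
  )
  structure(list(
    n_patients = as.integer(n_patients),
    smoker_fraction = smoker_fraction,
    hpv_pos_fraction = hpv_pos_fraction,
    burden_mean_nonsmoker = burden_mean_nonsmoker,
    burden_fold_smoker = burden_fold_smoker,
    tp53_rate_hpv_neg = tp53_rate_hpv_neg,
    tp53_rate_hpv_pos = tp53_rate_hpv_pos,
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' Simulate a patient cohort with mutation burdens
#'
#' Draws per-patient covariates and Poisson mutation counts under
#' [cohort_params()]. Total burden and TP53 count are drawn independently;
#' this keeps the two group comparisons (smoking vs burden, HPV vs TP53)
#' orthogonal by construction.
#'
#' @param params A [cohort_params()] object.
#' @return A list with `clinical` (tibble `sample_id`, `smoker`,
#'   `hpv_positive`) and `burdens` (tibble `sample_id`, `n_mutations`,
#'   `n_tp53`).
#' @examples
#' sim <- simulate_cohort(cohort_params(n_patients = 100, seed = 3))
#' dplyr::count(sim$clinical, smoker)
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  withr::with_seed(params$seed, {
    smoker <- runif(n) < params$smoker_fraction
    hpv <- runif(n) < params$hpv_pos_fraction
    mean_burden <- ifelse(smoker,
                          params$burden_mean_nonsmoker *
                            params$burden_fold_smoker,
                          params$burden_mean_nonsmoker)
    tp53_rate <- ifelse(hpv, params$tp53_rate_hpv_pos,
                        params$tp53_rate_hpv_neg)
    ids <- sprintf("P%04d", seq_len(n))
    list(
      clinical = tibble(sample_id = ids, smoker = smoker,
                        hpv_positive = hpv),
      burdens = tibble(sample_id = ids,
                       n_mutations = rpois(n, mean_burden),
                       n_tp53 = rpois(n, tp53_rate))
    )
  })
}

#' Write a deterministic fixture suite
#'
#' Emits a small, fully reproducible benchmark to `outdir`: a panel BED, a
#' matched tumor/normal pileup pair, a blacklist (the first half of the
#' planted artifact loci, mimicking partially known systematic positives),
#' the simulation truth table, a clinical covariate table and the
#' generating parameters as YAML.
#'
#' @param outdir Output directory (created if absent).
#' @param params A [sim_params()]; the default is a scaled-down benchmark
#'   (400 loci, median coverage 600) that exercises every filter.
#' @param cparams A [cohort_params()] for the clinical table.
#' @return A manifest tibble (`file`, `bytes`, `md5`), invisibly the same
#'   files on disk. Re-running with identical parameters reproduces
#'   identical checksums.
#' @export
write_fixture_suite <- function(outdir,
                                params = sim_params(
                                  n_loci = 400, median_coverage = 600,
                                  n_somatic = 3, n_germline = 6,
                                  n_artifact_loci = 4,
                                  low_coverage_fraction = 0.05, seed = 20140325),
                                cparams = cohort_params(seed = params$seed)) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) {
      abort(sprintf("cannot create output directory %s", outdir))
    }
  }
  panel <- simulate_panel(params$n_loci, n_genes = max(2L, params$n_loci %/% 100L))
  sim <- simulate_pair(panel, params)
  artifacts <- sim$truth[sim$truth$class == "artifact", ]
  blacklist <- artifacts[seq_len(nrow(artifacts) %/% 2), c("chrom", "pos")]
  cohort <- simulate_cohort(cparams)

  paths <- c(
    panel = file.path(outdir, "panel.bed"),
    tumor = file.path(outdir, "tumor.pileup.tsv"),
    normal = file.path(outdir, "normal.pileup.tsv"),
    blacklist = file.path(outdir, "blacklist.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    clinical = file.path(outdir, "clinical.tsv"),
    params = file.path(outdir, "params.yaml")
  )
  write_panel_bed(panel, paths["panel"])
  write_pileup(sim$tumor, paths["tumor"])
  write_pileup(sim$normal, paths["normal"])
  write_blacklist(blacklist, paths["blacklist"])
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  clinical <- dplyr::left_join(cohort$clinical, cohort$burdens,
                               by = "sample_id")
  readr::write_tsv(clinical, paths["clinical"], progress = FALSE)
  yaml::write_yaml(list(pair = unclass(params), cohort = unclass(cparams)),
                   paths["params"])

  tibble(
    file = unname(paths),
    bytes = unname(file.size(paths)),
    md5 = unname(tools::md5sum(paths))
  )
}
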