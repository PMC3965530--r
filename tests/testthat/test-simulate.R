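test_that("nothing planted means an empty truth table", {
  panel <- simulate_panel(300, 3)
  sim <- simulate_pair(panel, sim_params(
    n_loci = 300, n_somatic = 0, n_germline = 0, n_artifact_loci = 0,
    seed = 11))
  expect_equal(nrow(sim$truth), 0)
})

test_that("identical seeds give bitwise-identical pileups and truth", {
  panel <- simulate_panel(300, 3)
  p <- sim_params(n_loci = 300, seed = 99)
  a <- simulate_pair(panel, p)
  b <- simulate_pair(panel, p)
  expect_identical(a, b)
  c <- simulate_pair(panel, sim_params(n_loci = 300, seed = 100))
  expect_false(identical(a$tumor, c$tumor))
})

test_that("planted classes are disjoint and conserved in the truth table", {
  panel <- simulate_panel(500, 5)
  p <- sim_params(n_loci = 500, n_somatic = 7, n_germline = 13,
                  n_germline_hom = 2, n_artifact_loci = 5, seed = 3)
  sim <- simulate_pair(panel, p)
  expect_equal(as.vector(table(sim$truth$class)[c("artifact", "germline", "somatic")]),
               c(5L, 15L, 7L))
  expect_equal(anyDuplicated(sim$truth[c("chrom", "pos")]), 0L)
})

test_that("germline allele fractions match the binomial sampling model", {
  # constant depth 10000, no sequencing error: the mean alternate fraction
  # over 50 het loci must lie within 3 binomial standard errors of 0.5
  panel <- simulate_panel(200, 2)
  p <- sim_params(n_loci = 200, median_coverage = 10000,
                  coverage_dispersion = Inf, base_error_rate = 0,
                  n_germline = 50, n_somatic = 0, n_artifact_loci = 0,
                  low_coverage_fraction = 0, seed = 5)
  sim <- simulate_pair(panel, p)
  germ <- dplyr::inner_join(sim$tumor,
                            sim$truth[sim$truth$class == "germline",
                                      c("chrom", "pos", "alt_base")],
                            by = c("chrom", "pos"))
  counts <- as.matrix(germ[c("count_A", "count_C", "count_G", "count_T")])
  alt <- counts[cbind(seq_len(nrow(germ)),
                      match(germ$alt_base, c("A", "C", "G", "T")))]
  vaf_mean <- mean(alt / germ$depth)
  se <- sqrt(0.25 / (50 * 10000))
  expect_lt(abs(vaf_mean - 0.5), 3 * se)
})

test_that("artifact loci show elevated alternate fractions over baseline", {
  panel <- simulate_panel(1000, 5)
  sim <- simulate_pair(panel, sim_params(
    n_loci = 1000, n_somatic = 0, n_germline = 0, n_artifact_loci = 30,
    low_coverage_fraction = 0, seed = 8))
  art_key <- paste(sim$truth$chrom, sim$truth$pos)
  counts <- as.matrix(sim$tumor[c("count_A", "count_C", "count_G", "count_T")])
  ridx <- match(sim$tumor$ref_base, c("A", "C", "G", "T"))
  counts[cbind(seq_len(nrow(counts)), ridx)] <- 0L
  vaf <- rowSums(counts) / pmax(sim$tumor$depth, 1)
  is_art <- paste(sim$tumor$chrom, sim$tumor$pos) %in% art_key
  expect_gt(mean(vaf[is_art]), mean(vaf[!is_art]))
})

test_that("degenerate parameters are rejected", {
  expect_error(sim_params(base_error_rate = -0.1))
  expect_error(sim_params(artifact_error_rate = 0.001,
                          base_error_rate = 0.002))
  expect_error(sim_params(somatic_vaf_range = c(0.5, 0.1)))
  expect_error(sim_params(seed = NaN))
  expect_error(cohort_params(n_patients = 0))
  panel <- simulate_panel(50, 2)
  expect_error(simulate_pair(panel, sim_params(n_loci = 500)), "positions")
  expect_error(simulate_pair(panel, sim_params(n_loci = 50, n_somatic = 60)),
               "planted")
})

test_that("cohort generator recovers planted group means at large n", {
  sim <- simulate_cohort(cohort_params(n_patients = 5000,
                                       burden_fold_smoker = 1, seed = 17))
  d <- dplyr::left_join(sim$clinical, sim$burdens, by = "sample_id")
  means <- tapply(d$n_mutations, d$smoker, mean)
  expect_lt(abs(means[["TRUE"]] / means[["FALSE"]] - 1), 0.2)

  sim2 <- simulate_cohort(cohort_params(n_patients = 5000, seed = 17))
  d2 <- dplyr::left_join(sim2$clinical, sim2$burdens, by = "sample_id")
  means2 <- tapply(d2$n_mutations, d2$smoker, mean)
  expect_lt(abs(means2[["TRUE"]] / means2[["FALSE"]] / 3.2 - 1), 0.1)
  rates <- tapply(d2$n_tp53, d2$hpv_positive, mean)
  expect_lt(abs(rates[["FALSE"]] / rates[["TRUE"]] / (0.43 / 0.11) - 1), 0.15)
})

test_that("fixture suite is complete, deterministic and conserves events", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- write_fixture_suite(dir1)
  m2 <- write_fixture_suite(dir2)
  expect_gte(nrow(m1), 5)
  expect_true(all(file.exists(m1$file)))
  expect_equal(unname(m1$md5), unname(m2$md5))

  truth <- readr::read_tsv(file.path(dir1, "truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), 3 + 6 + 4)  # somatic + germline + artifact

  # the emitted pair is analyzable end to end
  tumor <- read_pileup(file.path(dir1, "tumor.pileup.tsv"))
  normal <- read_pileup(file.path(dir1, "normal.pileup.tsv"))
  panel <- read_panel_bed(file.path(dir1, "panel.bed"))
  bl <- read_blacklist(file.path(dir1, "blacklist.tsv"))
  calls <- call_somatic(tumor, normal, panel, bl)
  expect_s3_class(calls, "somatic_calls")
})
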