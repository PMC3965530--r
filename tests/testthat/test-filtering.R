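test_that("sample median coverage follows the sort-and-average rule", {
  expect_equal(sample_median_coverage(make_pileup(c(100, 100, 100))), 100)
  expect_equal(sample_median_coverage(make_pileup(c(10, 1000, 100, 500))), 300)
  expect_equal(sample_median_coverage(make_pileup(7)), 7)
  expect_error(sample_median_coverage(make_pileup(integer(0))), "empty")
})

test_that("coverage gate applies both arms strictly", {
  cfg <- filter_config()
  gate1 <- coverage_gate(make_pileup(101), median_cov = 1000, cfg)
  expect_true(gate1)                       # 101 > 100 and 101 > 20
  expect_false(coverage_gate(make_pileup(150), 10000, cfg))  # fails 2% arm
  expect_false(coverage_gate(make_pileup(100), 100, cfg))    # boundary: strict
})

test_that("variant score matches the exact binomial tail oracle", {
  expect_equal(variant_score(100, 0, 0.005), 0)
  expect_equal(variant_score(100, 1, 0.005),
               -10 * log10(1 - 0.995^100), tolerance = 1e-10)
  for (case in list(c(100, 1), c(100, 5), c(100, 50), c(1000, 20),
                    c(1000, 80), c(57, 3))) {
    expect_equal(variant_score(case[1], case[2], 0.005),
                 oracle_score(case[1], case[2], 0.005),
                 tolerance = 1e-8,
                 label = sprintf("score(%d, %d)", case[1], case[2]))
  }
  # monotone non-decreasing in alt at fixed depth
  scores <- variant_score(rep(100, 101), 0:100, 0.005)
  expect_true(all(diff(scores) >= 0))
  expect_gt(variant_score(100, 50, 0.005), variant_score(100, 5, 0.005))
  expect_error(variant_score(100, 150, 0.005), "exceed")
})

test_that("germline flag follows the strict 1 percent normal-VAF rule", {
  cfg <- filter_config()
  expect_true(germline_flagged(100, 2, cfg))    # 2% > 1%
  expect_false(germline_flagged(200, 0, cfg))   # zero evidence
  expect_false(germline_flagged(100, 1, cfg))   # exactly 1%: strict >
  expect_true(germline_flagged(0, 0, cfg))      # zero depth: conservative
})

test_that("background distribution matches a per-locus brute-force loop", {
  panel <- simulate_panel(600, 3)
  sim <- simulate_pair(panel, sim_params(n_loci = 600, n_somatic = 2,
                                         n_germline = 4, n_artifact_loci = 3,
                                         low_coverage_fraction = 0, seed = 21))
  cfg <- filter_config()
  pair <- somaticpair:::join_pair(sim$tumor, sim$normal)
  med_t <- median(pair$tumor_depth); med_n <- median(pair$normal_depth)
  retained <- pair$tumor_depth > 0.02 * med_t & pair$tumor_depth > 100 &
    pair$normal_depth > 0.02 * med_n & pair$normal_depth > 100
  ta <- somaticpair:::top_alt_base(
    pair[c("tumor_count_A", "tumor_count_C", "tumor_count_G", "tumor_count_T")],
    pair$ref_base)
  candidate <- ta$count > 0 & ta$count / pair$tumor_depth >= cfg$candidate_vaf_min
  blk <- rep(FALSE, nrow(pair))

  got <- background_difference_distribution(pair, retained, candidate, blk, cfg)

  # independent per-locus recomputation
  bases <- c("A", "C", "G", "T")
  expected <- c()
  for (i in which(retained & !candidate)) {
    tc <- as.numeric(pair[i, paste0("tumor_count_", bases)])
    nc <- as.numeric(pair[i, paste0("normal_count_", bases)])
    pooled <- tc + nc
    pooled[bases == pair$ref_base[i]] <- -1
    b <- which.max(pooled)  # which.max takes the first tie: alphabetical
    expected <- c(expected,
                  oracle_score(pair$tumor_depth[i], tc[b], cfg$background_error) -
                    oracle_score(pair$normal_depth[i], nc[b], cfg$background_error))
  }
  expect_equal(got, sort(expected), tolerance = 1e-8)

  # planted somatic loci never contribute to the background
  som <- sim$truth[sim$truth$class == "somatic", ]
  som_idx <- match(paste(som$chrom, som$pos), paste(pair$chrom, pair$pos))
  expect_true(all(candidate[som_idx]))

  expect_error(
    background_difference_distribution(pair[1:150, ], retained[1:150],
                                       candidate[1:150], blk[1:150], cfg),
    "background loci")
})

test_that("systematic flag uses the interpolated percentile of the background", {
  cfg <- filter_config()
  expect_true(systematic_flagged(0, rep(0, 500), cfg))   # within a point mass
  expect_false(systematic_flagged(50, rep(0, 500), cfg)) # exceeds it
  withr::with_seed(42, {
    bg <- rnorm(1000)
    hi <- oracle_quantile(bg, 0.999)
    lo <- oracle_quantile(bg, 0.99)
    expect_false(systematic_flagged(hi, bg, cfg))
    expect_true(systematic_flagged(lo, bg, cfg))
    expect_equal(quantile(bg, 0.995, type = 7, names = FALSE),
                 oracle_quantile(bg, 0.995), tolerance = 1e-12)
  })
})

test_that("a pair with no somatic signal yields zero accepted calls", {
  panel <- simulate_panel(500, 3)
  sim <- simulate_pair(panel, sim_params(n_loci = 500, n_somatic = 0,
                                         n_germline = 10, n_artifact_loci = 5,
                                         seed = 31))
  tumor <- sim$tumor
  normal <- dplyr::mutate(sim$normal, sample_id = "NORMAL")
  # tumor identical to normal: every candidate is germline and systematic
  self <- dplyr::mutate(tumor, sample_id = "SELF")
  calls <- call_somatic(tumor, self, panel)
  expect_equal(sum(calls$accepted), 0)
})

test_that("the cascade accepts a clean planted somatic and flags a 5% VAF", {
  # 300 clean loci of background plus one strong somatic locus at 46%
  # read frequency and one sub-threshold locus at 5%
  n <- 302
  depth <- rep(1000L, n)
  tumor <- make_pileup(depth, alt = 0L, sample_id = "T",
                       pos = seq_len(n))
  normal <- make_pileup(depth, alt = 0L, sample_id = "N",
                        pos = seq_len(n))
  tumor$count_A[1] <- 540L; tumor$count_C[1] <- 460L
  tumor$count_A[2] <- 950L; tumor$count_C[2] <- 50L  # 5% VAF
  calls <- call_somatic(tumor, normal)
  strong <- calls[calls$pos == 1, ]
  expect_equal(strong$filters, "")
  expect_true(strong$accepted)
  weak <- calls[calls$pos == 2, ]
  expect_equal(weak$filters, "low_vaf")
  # accepted calls appear as PASS in VCF
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  rec <- grep("^chr1\t1\t", readLines(path), value = TRUE)
  expect_match(rec, "\tPASS\t")
})

test_that("blacklisted loci are flagged even with somatic-like signal", {
  n <- 301
  tumor <- make_pileup(rep(1000L, n), alt = 0L, sample_id = "T")
  normal <- make_pileup(rep(1000L, n), alt = 0L, sample_id = "N")
  tumor$count_A[1] <- 700L; tumor$count_C[1] <- 300L
  bl <- tibble::tibble(chrom = "chr1", pos = 1L)
  calls <- call_somatic(tumor, normal, blacklist = bl)
  expect_equal(calls$filters[calls$pos == 1], "blacklist")
})

test_that("raising thresholds never enlarges the accepted set", {
  panel <- simulate_panel(800, 4)
  sim <- simulate_pair(panel, sim_params(n_loci = 800, n_somatic = 6,
                                         somatic_vaf_range = c(0.04, 0.5),
                                         n_germline = 8, n_artifact_loci = 4,
                                         seed = 55))
  accepted_at <- function(vaf_min, nmax = 0.01) {
    cfg <- filter_config(tumor_vaf_min = vaf_min, normal_vaf_max = nmax,
                         candidate_vaf_min = 0.02)
    calls <- call_somatic(sim$tumor, sim$normal, panel, config = cfg)
    paste(calls$chrom[calls$accepted], calls$pos[calls$accepted])
  }
  sets <- lapply(c(0.02, 0.06, 0.10, 0.20), accepted_at)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  # lowering the allowed normal VAF can only shrink the accepted set
  loose <- accepted_at(0.06, 0.05)
  tight <- accepted_at(0.06, 0.001)
  expect_true(all(tight %in% loose))
})

test_that("recovery metrics equal a hand-tallied confusion matrix", {
  panel <- simulate_panel(500, 5)
  sim <- simulate_pair(panel, sim_params(n_loci = 500, seed = 77))
  calls <- call_somatic(sim$tumor, sim$normal, panel)
  m <- recovery_metrics(calls, sim$truth, n_loci = 500)
  som <- paste(sim$truth$chrom[sim$truth$class == "somatic"],
               sim$truth$pos[sim$truth$class == "somatic"])
  acc <- paste(calls$chrom[calls$accepted], calls$pos[calls$accepted])
  expect_equal(m$tp, length(intersect(acc, som)))
  expect_equal(m$fp, length(setdiff(acc, som)))
  expect_equal(m$fn, length(setdiff(som, acc)))
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
  expect_equal(m$ppv, m$tp / (m$tp + m$fp))

  none <- calls[calls$accepted & FALSE, ]
  m0 <- recovery_metrics(none, sim$truth)
  expect_equal(m0$sensitivity, 0)
  expect_true(is.na(m0$ppv))
})
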