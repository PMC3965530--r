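# Construct a minimal single-sample pileup from parallel vectors; counts
# default to all-reference reads, with `alt` reads moved onto `alt_base`.
make_pileup <- function(depth, alt = 0, sample_id = "S1",
                        ref_base = "A", alt_base = "C",
                        chrom = "chr1", pos = seq_along(depth)) {
  n <- length(depth)
  alt <- rep_len(alt, n)
  ref_base <- rep_len(ref_base, n)
  alt_base <- rep_len(alt_base, n)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  rows <- seq_len(n)
  counts[cbind(rows, match(alt_base, colnames(counts)))] <- as.integer(alt)
  ridx <- cbind(rows, match(ref_base, colnames(counts)))
  counts[ridx] <- counts[ridx] + as.integer(depth - alt)
  tibble::tibble(
    sample_id = sample_id, chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref_base = ref_base, depth = as.integer(depth),
    count_A = counts[, "A"], count_C = counts[, "C"],
    count_G = counts[, "G"], count_T = counts[, "T"]
  )
}

table3_path <- function() {
  system.file("extdata", "hnscc_mutations.tsv", package = "somaticpair")
}

# Independent oracle: Phred-scaled binomial upper tail by direct summation
# of density terms.
oracle_score <- function(depth, alt, p) {
  if (alt == 0) return(0)
  -10 * log10(sum(dbinom(alt:depth, depth, p)))
}

# Independent oracle: linear interpolation between closest order statistics
# (the type-7 definition), written out from the formula.
oracle_quantile <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Independent oracle: two-sided Fisher exact p by exhaustive enumeration of
# all 2x2 tables with the observed margins, summing hypergeometric
# probabilities no larger than the observed table's.
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
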