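---
title: "Calling somatic mutations from matched tumor/normal pileups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic mutations from matched tumor/normal pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticpair)
library(dplyr)
```

## The problem

Targeted deep sequencing of tumor DNA against the patient's matched normal
(lymphocyte) DNA produces per-locus read counts at depths where *every*
locus shows some non-reference reads. Distinguishing somatic point
mutations from germline variants, stochastic sequencing error and
recurrent systematic artifacts is therefore a filtering problem, not a
detection problem. `somaticpair` implements that filter cascade for
pileup count tables over a targeted panel of cancer genes (a mixture of
hotspot regions and whole coding exons), plus the downstream summaries a
cohort study reports: per-gene patient rates, gene-by-patient matrices,
and Fisher exact comparisons of mutation burden against clinical
covariates such as smoking and HPV status.

## The filter cascade

For a matched pair over the same loci, `call_somatic()` applies, in order:

1. **Coverage gate.** A locus is analyzable when its depth strictly
   exceeds both `min_reads` (default 100 reads) and `median_fraction`
   (default 2%) of that sample's median coverage, in *both* samples. Both
   comparisons are strict, following the rule's "greater than" wording; a
   depth of exactly 100 fails.
2. **Candidate nomination.** At each locus the most frequent
   non-reference tumor base (ties broken alphabetically, A<C<G<T) defines
   the candidate allele. The call threshold is `tumor_vaf_min = 0.06`:
   a mutation read frequency of exactly 6% is callable (inclusive), since
   the value is a threshold for acceptance. Loci reaching the nomination
   floor `candidate_vaf_min = 0.02` are *reported* as candidates so that
   near-threshold events are visible with a `low_vaf` flag rather than
   silently dropped; loci failing the gate are likewise reported with
   `low_coverage`. The floor sits an order of magnitude above what the
   default 0.2% base error can reach at benchmark depth
   (P[VAF ≥ 2% | depth 1000, p = 0.002] ≈ 3·10⁻⁵), so the background
   stays essentially uncontaminated.
3. **Blacklist.** Loci known to generate systematic positives across
   samples are flagged `blacklist` regardless of signal.
4. **Germline filter.** A candidate whose matched normal shows strictly
   more than `normal_vaf_max = 0.01` variant reads at the same base is
   flagged `germline`. A normal with zero depth cannot exclude germline
   origin and is flagged conservatively.
5. **Systematic-error filter.** Each side of the pair gets a Phred-scaled
   binomial variant score
   $$s(d, a) = -10 \log_{10} P[X \ge a], \qquad X \sim \mathrm{Bin}(d, p_0),$$
   with background error `background_error` $p_0 = 0.005$. The score is 0
   at $a = 0$ and monotone non-decreasing in $a$; it is computed in log
   space so deep loci with hundreds of alternate reads stay finite. For
   every retained locus that is neither a candidate nor blacklisted — the
   variant-free "background" — the tumor−normal score difference is
   collected, and a candidate whose own difference lies at or below the
   `diff_percentile = 99.5`th percentile of that distribution is flagged
   `systematic`. Signed differences are used (a systematic artifact
   inflates both samples, so its difference is small); ties at the
   percentile are flagged, the conservative choice.

A call is **accepted** exactly when its flag set is empty. The exact
variant-score formula used by the original assay is calibrated to that
assay's data; the binomial-tail definition here is a declared,
reproducible substitute with the properties that matter to the filter
(depth awareness, monotonicity in alternate reads), not a reconstruction.

### Numerical choices

* Percentiles use linear interpolation between the closest order
  statistics (`stats::quantile()` type 7), stated so that results are
  bit-reproducible; the test suite checks it against an independently
  written interpolation formula.
* Fewer than 200 background loci is an error: a 99.5th percentile
  estimated from less data is dominated by single order statistics.
* Fisher exact p-values are two-sided by probability-mass summation over
  all tables with the observed margins (via `stats::fisher.test()`,
  checked in the tests against an in-package exhaustive hypergeometric
  enumeration), not by doubling the one-sided tail.
* Printed-percentage comparisons round half away from zero at one
  decimal (`round_half_up()`), the convention of clinical tables;
  base R's `round()` rounds halves to even.

## Effect annotation

Accepted substitutions are classified from codon content with the
standard genetic code (`Biostrings::GENETIC_CODE`): `STOP_GAINED` when the
alternate codon is a stop and the reference is not, `SILENT` when both
translate identically, `NON_SYNONYMOUS` otherwise. Stop-loss is classified
`NON_SYNONYMOUS` with a warning — no such event occurs in the packaged
table. `SPLICE_SITE` belongs to the effect vocabulary but is a property of
the locus, never inferred from codons; it is carried through when an
external annotation supplies it. CDS changes use the compact dialect
`"aTc/aCc"`: one uppercase letter per codon marks the substituted
position, and parsing rejects anything else (wrong length, zero or two
capitals, disagreeing positions, identical codons, unmarked differences).

`verify_mutation_table()` re-derives every row's effect and protein-change
string from its CDS change and reports discrepancies. On the packaged
26-mutation HNSCC table it reports none:

```{r verify}
tbl <- read_mutation_table(system.file("extdata", "hnscc_mutations.tsv",
                                       package = "somaticpair"))
verify_mutation_table(tbl)
```

One documented inconsistency in the source cohort is *not* resolvable
from the table itself: the cohort text counts 17 of 37 patients with
mutations, while the mutation list contains 18 distinct sample IDs.
`glance(summarize_mutations(...))` reports what the table supports (18);
the discrepancy is surfaced, not silently corrected. Similarly, the
source describes its HPV-stratified TP53 rates (0.43 HPV-negative vs 0.11
HPV-positive mutations per sample) as "4-fold lower" where its own
numbers give a ~3.9-fold *higher* rate in HPV-negative patients; the
package reports per-group rates plus a max/min `rate_ratio`, leaving
orientation explicit in the per-group rows.

## What the simulator emulates — and what it does not

`simulate_pair()` generates the statistical structure the cascade
assumes, with known ground truth:

* **Coverage**: negative binomial with mean `median_coverage` and size
  `coverage_dispersion` (default 1000 and 10). Targeted amplicon coverage
  is strongly overdispersed relative to Poisson; dispersion 10 gives a
  coefficient of variation ≈ 0.33, typical of droplet-PCR enrichment.
  `coverage_dispersion = Inf` gives constant depth, used by the test
  oracle for binomial sampling checks. A `low_coverage_fraction`
  (default 5%) of baseline loci is forced below the retention thresholds
  to exercise the gate.
* **Errors**: binomial draws at a fixed per-locus rate (default 0.2%,
  consistent with post-quality-trimmed data) onto a single pre-chosen
  alternate base per locus. There is no per-base quality model — quality
  trimming is upstream of this pipeline's inputs.
* **Germline** heterozygous loci: binomial at VAF 0.5 in *both* samples
  (default 20 per pair). Homozygous loci (VAF 1) exist behind
  `n_germline_hom` but default to 0: the germline filter treats het and
  hom identically, so they add nothing to the benchmark.
* **Somatic** loci: tumor only, VAF uniform in `somatic_vaf_range`
  (default [0.08, 0.5] — comfortably above the 6% threshold and spanning
  orthogonally validated read frequencies of 14–46%); the normal keeps
  base-rate error (default 5 per pair).
* **Artifacts**: an elevated error rate (default 2%) shared by both
  samples at `n_artifact_loci` loci (default 10), emulating systematic
  positives. These are the filter cascade's hardest case: their normal
  signal usually triggers the germline flag and their small score
  difference the systematic flag.

Not modelled: read-level artifacts (mapping, strand bias), FFPE
deamination, indels, multi-allelic loci, contamination, and any
correlation structure between loci. Consequently, a passing benchmark
demonstrates that the cascade's *rules* behave as specified under the
assumed noise model — it does not certify performance on real reads,
where artifact modes the generator omits would reduce PPV. The planted
event classes are disjoint by construction and every event appears
exactly once in the truth table, which is what makes
sensitivity/PPV/specificity well defined.

`simulate_cohort()` draws per-patient covariates (smoker, HPV) and
Poisson mutation burdens: non-smokers at `burden_mean_nonsmoker = 0.25`
mutations/sample, smokers `burden_fold_smoker = 3.2` times higher; TP53
counts at 0.43 (HPV-negative) vs 0.11 (HPV-positive). Total burden and
TP53 count are drawn independently — a deliberate simplification that
keeps the two group comparisons orthogonal, at the cost of allowing a
patient's TP53 count to exceed their total burden in principle; the
comparisons never combine the two columns, so nothing downstream depends
on that coupling. Per-sample covariate assignments of the original cohort
were never published in tabular form, so these are simulation inputs, not
reconstructions.

## Problem sizes

The shipped benchmark and tests use sizes chosen to make every
distributional check well-powered while staying comfortably
desk-computable: 50 pairs × 2000 loci for the PPV benchmark (250 planted
somatic events pooled), 500–1000 loci for property sweeps, 5000 patients
for cohort parameter recovery (relative error of a Poisson mean at
n ≈ 3000 per group is ~2%, well inside the 10–15% recovery tolerances),
and the full 9 × 64 single-base codon-change space for the effect
classifier, checked exhaustively against an independent translation
oracle.

```{r benchmark}
panel <- simulate_panel(2000, 20)
sim <- simulate_pair(panel, sim_params(seed = 1))
calls <- call_somatic(sim$tumor, sim$normal, panel)
recovery_metrics(calls, sim$truth, n_loci = nrow(sim$tumor))
```

## Known limitations

* The cascade assumes one alternate base per locus; true multi-allelic
  sites would be reduced to their dominant alternate.
* The background distribution conditions on the pair at hand; very small
  panels (< 200 background loci) cannot support the 99.5th percentile and
  are rejected rather than extrapolated.
* Specificity from `recovery_metrics()` treats every non-somatic locus as
  a negative; at benchmark scale it is dominated by easy negatives and is
  mainly useful for regression tracking, PPV being the informative
  statistic.
* `SPLICE_SITE` effects require external locus annotation; the in-package
  classifier alone can only produce the three codon-level classes.
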