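Package: somaticpair
Title: Matched Tumor-Normal Somatic Mutation Calling from Targeted Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A filter cascade for calling somatic point mutations from
    matched tumor/normal pileup count tables over a targeted cancer gene
    panel: coverage gating against the sample median, germline subtraction
    through the matched normal, a blacklist of known systematic positives,
    and a percentile filter on Phred-scaled variant-score differences that
    removes sample-specific systematic errors. Includes a seeded generator
    of paired pileups with negative-binomially overdispersed coverage and
    planted somatic, germline and artifact loci for benchmarking
    sensitivity and positive predictive value; a codon-level effect
    classifier (missense, nonsense, silent, splice site) with
    protein-change notation; and mutation-landscape summaries
    (gene-by-patient matrices, per-gene patient rates, Fisher exact group
    comparisons of mutation burden).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    VariantAnnotation,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
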