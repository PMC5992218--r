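Package: polefoot
Title: Mutation-Footprint Analysis of POLE Proofreading-Deficient Hypermutator Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracing the temporal footprint of POLE
    exonuclease-domain hypermutation in somatic mutation catalogs.
    Classifies tumours into non-hypermutator, common hypermutator and
    POLE-category subtypes from nonsynonymous SNV burden and trinucleotide
    substitution patterns; tallies the 96 canonical trinucleotide context
    classes; computes per-gene propensity scores (PS) contrasting the
    frequency of TCT>TAT and TCG>TTG propensity mutations between tumour
    groups; locates the inflection point of the PS quantile-quantile plot
    by one-break segmented regression with a Davies-type significance test
    and a bootstrap confidence interval; assigns genes to POLE-independent,
    indefinite and POLE-dependent temporal periods; and scores homologous
    recombination and non-homologous end-joining expression signatures.
    Includes a synthetic-cohort generator with per-mutation ground truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests:
    Biostrings,
    vcfR,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
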