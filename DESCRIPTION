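Package: vartag
Title: Read-Level Metrics, Tagging and Scoring for Variant Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated refinement of germline and somatic variant calls from
    read-level evidence. For each candidate variant the package retrieves the
    covering reads from an indexed alignment, classifies per-read support via
    the CIGAR, computes 16 (germline) or 18 (somatic) pileup metrics that
    capture the classic manual-review artifact modes (low coverage, low
    allele frequency, positional clustering, strand bias, duplicate
    signatures, low mapping quality, linked secondary mismatches, adjacent
    indels, repeat contexts, mate-overlap-only support, normal-track
    contamination), marks 19 review tags, and summarises them in a weighted
    v-score where low scores indicate likely true variants. Includes
    F-beta threshold-sweep evaluation, a gradient-boosted refinement
    classifier with grid-searched cross-validation, and a synthetic
    paired-end pileup generator so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Biostrings,
    vcfR,
    xgboost,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
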