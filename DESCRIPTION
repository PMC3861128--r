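Package: crosstol
Title: Cross-Drug Epigenomic Discovery of Alcohol-Tolerance Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for finding candidate functional-tolerance genes
    from drug-induced histone-acetylation changes measured on two-channel tiling
    arrays. Provides variance-stabilized log-ratio tracks and drug-vs-control
    difference tracks, permutation-calibrated peak calling with a false
    discovery rate threshold and an enrichment-score filter, distance-rule
    peak-to-gene assignment with cross-drug cohort intersection, co-expression
    clustering (centered Pearson, SOM seeding, complete linkage) with
    cluster-cohesion flagging, offline annotation-term enrichment (Fisher exact
    and EASE scores), Richards-curve quantification of behavioral tolerance
    with Dunnett comparisons, delta-delta-Ct qPCR quantification, and
    array-vs-qPCR cross-validation. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable without
    any array download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    minpack.lm,
    multcomp,
    nortest,
    fgsea,
    rtracklayer,
    GenomicRanges,
    IRanges,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
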