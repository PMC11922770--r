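Package: methylnb
Title: Weighted Bernoulli Naive Bayes Classification of Tumor Methylomes
    from Sparse Single-Molecule CpG Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains centroid-based, ReliefF-weighted Bernoulli naive Bayes
    reference models on bulk methylation-rate matrices (450k/EPIC-array style
    beta tables) and classifies tumor samples from extremely sparse, binary
    single-molecule CpG methylation observations, such as those produced in
    the first minutes of a nanopore sequencing run. Includes reference-matrix
    preparation (probe filtering, batch correction, cohort merging), ingestion
    of aligned reads carrying MM/ML base-modification tags, a synthetic-data
    simulator for shallow methylome profiles, tiered (fine / clinical group /
    class family) evaluation with threshold sweeps and time-course analysis,
    and offline as well as live directory-watching classification entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
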