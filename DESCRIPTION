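Package: cyclotome
Title: Periodicity Detection and Comparative Analysis of Cell-Cycle
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synchronized-culture cell-cycle time-course
    transcriptomes. Detects periodically expressed genes with two rank-based
    tests (Kendall-tau correlation against discretized cosine reference
    waveforms, and a rank umbrella test for rise-to-peak-then-fall shapes),
    combines them by rank sums with replicate-consistency cutoffs, clusters
    the periodic genes into temporal expression waves, assigns evolutionary
    gene ages by Dollo parsimony over orthogroup presence/absence on a rooted
    species tree, performs term over-representation tests including a
    parent-child-union mode, and tests cross-species overlap of periodic
    orthogroups against an explicit binomial null. A synthetic-data module
    generates damped-oscillation time courses, orthogroup universes and
    gene-family histories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
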