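Package: phoregulon
Title: Reconstruction of a Phosphate-Starvation Regulon from Two-Color
    Arrays and ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for reconstructing the fission-yeast
    phosphate-starvation (PHO) regulon. Processes two-color expression arrays
    (lowess and quantile normalization, pooled-reference time-course ratios,
    median + 2-sigma induction thresholds, rapid/slow temporal classification,
    one-tailed differential calls, k-means profile clustering), calls
    transcription-factor binding peaks from extended-read ChIP-Seq coverage by
    an iterative multi-threshold sweep with mock-IP Poisson filtering, links
    retained peaks to 800-bp promoter windows, and scores regulated-set versus
    bound-set overlap with an exact hypergeometric tail test. Includes a
    synthetic-data generator (toy genomes, arrays, read sets, FACS events)
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
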