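Package: dipcaller
Title: Nonparametric ChIP-Seq Peak Calling Against a Matched-Control Empirical Null
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls protein-binding peaks from ChIP-seq read tracks by scoring
    fixed-length genomic segments against an empirical null distribution built
    jointly from the immunoprecipitation (IP) and matched control (e.g. IgG)
    tracks. For every segment the IP read count (magnitude) is compared with
    the genome-wide distribution of magnitudes at the same total read count
    (amplitude); segments in the upper tail at a chosen false discovery rate
    are merged into candidate regions, filtered on length and control-read
    fraction, and scored with a Kullback-Leibler divergence statistic. Includes
    a synthetic read simulator with a shared non-uniform background plus
    spiked IP-only enrichment peaks, and evaluation utilities (promoter
    assignment, Jaccard reproducibility, truth-based precision/recall).
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
    purrr,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
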