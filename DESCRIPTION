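Package: oralcore
Title: Core and Non-Core Functional Gene Analysis of Saliva Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for functional-gene microarray profiles of
    human saliva microbiota in healthy versus caries-active hosts. Provides
    signal-intensity/SNR positive calling, per-sample normalization, a
    core versus non-core gene partition, diversity indices with permutation
    t-tests, gene-sharing and saturation-curve statistics, co-presence
    network construction with module detection, correspondence analysis with
    detrending by segments, multi-response permutation procedure (MRPP)
    tests, and a presence/absence triplet-feature biomarker procedure with
    exclusive-pattern gene detection. A synthetic data generator emulating
    the structure of functional gene arrays supplies ground-truthed inputs
    so that every stage is testable without raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
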