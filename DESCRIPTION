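Package: pifnet
Title: Promoter-Interaction Networks and Non-Coding Somatic Driver Analysis in Melanoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a promoter-interaction network over restriction fragments
    from processed Hi-C interaction files, characterises promoter-interacting
    fragments (sequence constraint, histone-mark enrichment, somatic mutation
    rates), scans promoter fragments and non-coding promoter-interacting
    fragments for recurrent somatic mutation hotspots against a covariate-aware
    background model, tests hotspots as somatic eQTLs with Lasso-assisted
    multivariate regression, and scores transcription-factor motif disruption
    by hotspot SNVs. Ships a synthetic-cohort generator with planted network
    edges, hotspots and eQTL effects so the whole pipeline is testable without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
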