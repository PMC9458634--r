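Package: ramscan
Title: Chromatin Module Calling from Histone-Mark Peak Density Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls regulation-associated modules (RAMs) directly from
    histone-modification ChIP-seq peak calls: sliding-window peak-density
    profiles are smoothed by tricube-weighted local polynomial regression and
    segmented at density valleys, and per-sample boundary calls are aggregated
    into cohort consensus modules (cRAMs). Includes interval statistics for
    domain sets (intra-domain fractions of anchor pairs and intervals, boundary
    overlap and recall, boundary-versus-background density contrast,
    compartment composition), Hi-C contact utilities (vanilla-coverage
    normalization, Poisson contact significance, contact degree, A/B
    compartment assignment), enrichment tests (hypergeometric upper tail,
    pooled two-sample proportion test), and a synthetic-data generator with a
    known modular ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
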