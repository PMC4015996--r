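Package: factoscreen
Title: Factorial Design-of-Experiments Analysis of Digital mRNA Count Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for two-level full factorial
    ("quality-by-design") screening of differentiation conditions profiled
    with digital mRNA counting (NanoString nCounter-like panels).
    Provides design construction for a five-factor 2^5 screen with isoform
    and seeding-density arms, spike-in and reference-gene count
    normalization (NormFinder-style stability selection, generalized log
    transform), studentized wanted/unwanted marker-panel scoring, factorial
    main-effect and interaction inference with normal plots, empirical-Bayes
    moderated differential expression with fold-change/FDR calling,
    competitive gene-set enrichment ranking of conditions, principal
    component views, and a negative-binomial count simulator with planted
    effect structure for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
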