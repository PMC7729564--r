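Package: quiescreen
Title: High-Throughput Flow Cytometry Analysis of Yeast Quiescence Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plate-format flow-cytometry screens of
    cellular quiescence in fission yeast deletion libraries. Provides
    event-level gating (doublet exclusion, live/dead classification, and
    DNA-content classification of live singlets into G0, G2, and binuclear
    G1/M), nonlinear mortality-curve fitting over seven kinetic models with
    rule-based model selection and half-life (T1/2, T1/4) extrapolation with
    bootstrap confidence intervals, five-feature hierarchical clustering of
    mutant phenotypes with Ward's method and cluster-number selection by the
    Cubic Clustering Criterion, and cluster-wise protein-complex enrichment
    statistics (fold enrichment and hypergeometric probabilities). A
    synthetic-cytometry module simulates plate-format event tables with
    known ground truth so every stage of the pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
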