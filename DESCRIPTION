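Package: sigbenefit
Title: Mutational-Signature Prediction of Durable Immunotherapy Benefit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that predicts durable benefit from
    immunotherapy in advanced non-small cell lung cancer using somatic
    mutational signatures. Extracts SBS-96 trinucleotide mutation spectra
    from variant calls, refits them against a fixed signature catalog by
    non-negative least squares (coordinate descent), screens signature
    attributions against outcome with Kolmogorov-Smirnov and Kendall
    tau statistics under Benjamini-Hochberg correction, classifies
    patients with a zero-inflated-exponential naive Bayes model under
    leave-one-out cross-validation, and evaluates predictions with
    bootstrap confidence intervals, permutation tests, Kaplan-Meier and
    Cox survival analysis, and decision-curve (net benefit) analysis.
    Includes a synthetic-cohort generator with the generative structure
    the analysis assumes, so the full pipeline is testable without
    access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
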